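#' Exposure metrics from a concentration-time course
#'
#' AUC by the linear trapezoid rule over the sampled interval, terminal
#' half-life from a log-linear regression on the terminal declining phase
#' (the longest run of strictly decreasing positive concentrations at the
#' end of the profile, at least 3 points; `NA` when absent), and, when a
#' tissue column is supplied, the tissue-to-blood exposure ratio
#' `Kp = AUC_tissue / AUC_blood`.
#'
#' @param data Tibble with columns `time` (h, ascending within profile),
#'   `conc` (nM), and optionally `tissue`.
#' @param reference_tissue Tissue name used as the Kp denominator
#'   (default `"blood"`).
#' @return Tibble with one row per tissue (or a single row):
#'   `tissue, auc, half_life, kp`, AUC in nM h, half-life in h.
#' @export
#' @examples
#' exposure_metrics(data.frame(time = 0:48, conc = rep(10, 49)))$auc # 480
exposure_metrics <- function(data, reference_tissue = "blood") {
  stop_if_missing_cols(data, c("time", "conc"), "data")
  if (!"tissue" %in% names(data)) data$tissue <- "all"
  res <- data %>%
    group_by(.data$tissue) %>%
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$time, strictly = FALSE)) {
        abort("times must be sorted ascending within each profile")
      }
      tibble(auc = pracma::trapz(df$time, df$conc),
             half_life = terminal_half_life(df$time, df$conc))
    }) %>%
    ungroup()
  if (reference_tissue %in% res$tissue) {
    ref_auc <- res$auc[res$tissue == reference_tissue]
    res$kp <- res$auc / ref_auc
  } else {
    res$kp <- NA_real_
  }
  res
}

# longest strictly-declining run of positive concentrations ending at the
# last sample; log-linear slope -> t1/2 = ln 2 / k
terminal_half_life <- function(time, conc) {
  n <- length(conc)
  if (n < 3) return(NA_real_)
  i <- n
  while (i > 1 && conc[i - 1] > conc[i] && conc[i] > 0) i <- i - 1
  idx <- i:n
  idx <- idx[conc[idx] > 0]
  if (length(idx) < 3) return(NA_real_)
  k <- -unname(coef(lm(log(conc[idx]) ~ time[idx]))[2])
  if (!is.finite(k) || k <= 0) return(NA_real_)
  log(2) / k
}

#' Tumour-response metrics from longitudinal volumes
#'
#' Percent change from baseline `100 * (V(t) - V0) / V0` per time point,
#' best response (the minimum percent change over follow-up, as plotted in
#' waterfall plots), and the exponential growth rate per day (least-squares
#' slope of `ln V` versus time).
#'
#' @param data Tibble with columns `tumour_id, time, volume` (days, mm^3);
#'   the earliest time point per tumour is the baseline and must be > 0.
#' @return Tibble with one row per tumour: `tumour_id, baseline,
#'   best_response, growth_rate`, plus a `timecourse` list-column of
#'   per-time percent changes.
#' @export
tumour_response <- function(data) {
  stop_if_missing_cols(data, c("tumour_id", "time", "volume"), "data")
  data %>%
    group_by(.data$tumour_id) %>%
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$time)
      v0 <- df$volume[1]
      if (!is.finite(v0) || v0 <= 0) abort("baseline volume must be > 0")
      pct <- 100 * (df$volume - v0) / v0
      gr <- if (nrow(df) >= 2 && all(df$volume > 0)) {
        unname(coef(lm(log(df$volume) ~ df$time))[2])
      } else NA_real_
      tibble(baseline = v0,
             best_response = min(pct[-1], pct[1]),
             growth_rate = gr,
             timecourse = list(tibble(time = df$time, pct_change = pct)))
    }) %>%
    ungroup()
}
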