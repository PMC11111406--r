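#' Control separability of a cell line on one plate
#'
#' Quantifies how well a simple threshold separates a line's
#' positive-control (lethal) from negative-control (vehicle) measurements.
#' The error rate is the minimum over all thresholds t of `(FP + FN) / n`,
#' where everything below t is called positive and everything above negative,
#' FP counts negative-control values below t, FN counts positive-control
#' values at or above t, and n is the total number of controls. Candidate
#' thresholds are the midpoints between adjacent distinct pooled values plus
#' -Inf and +Inf. The dynamic range is `median(neg) - median(pos)` in log2
#' units.
#'
#' @param neg Numeric vector of negative-control values (log2 MFI).
#' @param pos Numeric vector of positive-control values.
#' @return One-row tibble: `error_rate, dynamic_range, threshold`.
#' @export
#' @examples
#' control_separability(neg = c(5, 6), pos = c(1, 2)) # error 0, DR 4
control_separability <- function(neg, pos) {
  if (length(neg) == 0 || length(pos) == 0) {
    abort("both control sets must be non-empty")
  }
  vals <- sort(unique(c(neg, pos)))
  cand <- c(-Inf, if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2,
            Inf)
  n <- length(neg) + length(pos)
  err <- vapply(cand, function(t) {
    fp <- sum(neg < t)
    fn <- sum(pos >= t)
    (fp + fn) / n
  }, numeric(1))
  i <- which.min(err)
  tibble(error_rate = err[i],
         dynamic_range = median(neg) - median(pos),
         threshold = cand[i])
}

#' Apply screen inclusion filters to per-replicate QC metrics
#'
#' A cell line x replicate passes when its error rate is at most `error_max`
#' and its dynamic range at least `dr_min` (boundary values pass; the
#' exclusion rules are strictly "above" / "less than"). A cell line is
#' included when it has at least `min_passing_replicates` passing replicates.
#'
#' @param qc Tibble with columns `cell_line, replicate, error_rate,
#'   dynamic_range` (one row per line x replicate plate).
#' @param error_max Maximum tolerated error rate (default 0.05).
#' @param dr_min Minimum tolerated dynamic range, log2 units (default 1.74).
#' @param min_passing_replicates Minimum passing replicates (default 2).
#' @return `qc` with logical columns `passes` (per replicate),
#'   `n_passing_replicates` and `included` (per line).
#' @export
apply_qc_filters <- function(qc, error_max = 0.05, dr_min = 1.74,
                             min_passing_replicates = 2) {
  stop_if_missing_cols(qc, c("cell_line", "replicate", "error_rate",
                             "dynamic_range"), "qc")
  qc %>%
    mutate(passes = .data$error_rate <= error_max &
             .data$dynamic_range >= dr_min) %>%
    group_by(.data$cell_line) %>%
    mutate(n_passing_replicates = sum(.data$passes),
           included = .data$n_passing_replicates >= min_passing_replicates) %>%
    ungroup()
}

#' Per-line, per-plate QC metrics from calibrated plate data
#'
#' Computes [control_separability()] for every cell line x plate from the
#' calibrated control-well signals.
#'
#' @param calibrated Calibrated cell-barcode tibble (see
#'   [calibrate_plates()]): needs `plate_id, replicate, treatment, barcode_id,
#'   corrected_log2_mfi`.
#' @return Tibble: `cell_line, plate_id, replicate, error_rate,
#'   dynamic_range, threshold`.
#' @export
screen_qc_metrics <- function(calibrated) {
  stop_if_missing_cols(calibrated,
                       c("plate_id", "replicate", "treatment", "barcode_id",
                         "corrected_log2_mfi"), "calibrated")
  calibrated %>%
    filter(.data$treatment %in% c("negative_control", "positive_control")) %>%
    group_by(cell_line = .data$barcode_id, .data$plate_id, .data$replicate) %>%
    dplyr::group_modify(function(df, key) {
      control_separability(
        neg = df$corrected_log2_mfi[df$treatment == "negative_control"],
        pos = df$corrected_log2_mfi[df$treatment == "positive_control"]
      )
    }) %>%
    ungroup()
}
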