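#' Excess-over-Bliss synergy scoring of a dose matrix
#'
#' On the inhibition scale `e = 1 - viability` (viability clipped to
#' \[0, 1\] first), the Bliss-independence expectation for a dose pair is
#' `eA + eB - eA * eB`, built from the single-agent (zero-dose) row and
#' column; the per-cell excess is `observed - expected`. Positive excess
#' means synergy. Replicates are scored individually (excess per replicate,
#' averaged afterwards).
#'
#' @param matrix_df Long tibble with columns `dose_a, dose_b, viability`
#'   and optionally `replicate`; must contain the zero-dose row and column
#'   (single agents) for every replicate.
#' @return Tibble of combination cells (`dose_a > 0 & dose_b > 0`):
#'   `dose_a, dose_b, replicate, viability, inhibition, expected, excess`.
#' @seealso [mean_synergy()]
#' @export
bliss_excess <- function(matrix_df) {
  stop_if_missing_cols(matrix_df, c("dose_a", "dose_b", "viability"),
                       "matrix_df")
  if (!"replicate" %in% names(matrix_df)) matrix_df$replicate <- 1L
  df <- matrix_df %>%
    mutate(inhibition = 1 - clip(.data$viability, 0, 1))
  single_a <- df %>% filter(.data$dose_b == 0, .data$dose_a > 0) %>%
    select("dose_a", "replicate", e_a = "inhibition")
  single_b <- df %>% filter(.data$dose_a == 0, .data$dose_b > 0) %>%
    select("dose_b", "replicate", e_b = "inhibition")
  if (nrow(single_a) == 0 || nrow(single_b) == 0) {
    abort("single-agent (zero-dose) row and column are required")
  }
  combos <- df %>% filter(.data$dose_a > 0, .data$dose_b > 0)
  out <- combos %>%
    inner_join(single_a, by = c("dose_a", "replicate")) %>%
    inner_join(single_b, by = c("dose_b", "replicate")) %>%
    mutate(expected = .data$e_a + .data$e_b - .data$e_a * .data$e_b,
           excess = .data$inhibition - .data$expected) %>%
    select("dose_a", "dose_b", "replicate", "viability", "inhibition",
           "expected", "excess")
  if (nrow(out) < nrow(combos)) {
    abort("missing single-agent measurement for some dose level/replicate")
  }
  out
}

#' Mean synergy of a scored dose matrix
#'
#' Average Bliss excess over all nonzero dose pairs (and replicates).
#'
#' @param excess_df Output of [bliss_excess()].
#' @return Single numeric mean synergy score.
#' @export
mean_synergy <- function(excess_df) {
  stop_if_missing_cols(excess_df, "excess", "excess_df")
  mean(excess_df$excess)
}

#' z-score differential expression signature of one treated sample
#'
#' Per-gene standard score of the treated sample's expression against the
#' vehicle-control replicates: `z(g) = (x(g) - mean_ctrl(g)) / sd_ctrl(g)`
#' with the sample standard deviation (denominator n - 1). Genes whose
#' control s.d. is zero are flagged and get `NA` z-scores.
#'
#' @param expr Wide tibble: a `gene` column plus one numeric column per
#'   sample.
#' @param treated Name of the treated sample column.
#' @param controls Character vector of control (vehicle) sample columns,
#'   at least 2.
#' @return Tibble: `gene, z, flagged` (flagged = zero control s.d.).
#' @export
#' @examples
#' e <- data.frame(gene = "G1", t1 = 12, c1 = 9, c2 = 10, c3 = 11)
#' zscore_signature(e, "t1", c("c1", "c2", "c3")) # z = 2
zscore_signature <- function(expr, treated, controls) {
  stop_if_missing_cols(expr, c("gene", treated, controls), "expr")
  if (length(controls) < 2) abort("need at least 2 control replicates")
  ctrl <- as.matrix(expr[, controls, drop = FALSE])
  mu <- rowMeans(ctrl)
  sdv <- apply(ctrl, 1, sd)
  flagged <- !is.finite(sdv) | sdv == 0
  z <- (expr[[treated]] - mu) / sdv
  z[flagged] <- NA_real_
  tibble(gene = expr$gene, z = z, flagged = flagged)
}

#' Consensus signature across cell lines or drugs
#'
#' Integrates single-sample z-score signatures over a shared gene universe.
#' The default is the Stouffer combination `z_cons = sum(z_i) / sqrt(k)`
#' over the k signatures with a defined value for the gene; `method =
#' "mean"` averages instead.
#'
#' @param signatures List of signature tibbles (`gene, z`), e.g. from
#'   [zscore_signature()].
#' @param method `"stouffer"` (default) or `"mean"`.
#' @return Tibble: `gene, z, n_signatures`.
#' @export
consensus_signature <- function(signatures, method = c("stouffer", "mean")) {
  method <- match.arg(method)
  stopifnot(length(signatures) >= 2)
  long <- purrr::imap_dfr(signatures, function(s, i) {
    stop_if_missing_cols(s, c("gene", "z"), "signature")
    tibble(gene = s$gene, z = s$z, src = i)
  })
  shared <- long %>% group_by(.data$gene) %>%
    summarise(n_signatures = sum(is.finite(.data$z)),
              z_sum = sum(.data$z[is.finite(.data$z)]),
              .groups = "drop") %>%
    filter(.data$n_signatures > 0)
  if (nrow(shared) == 0) abort("no genes shared across signatures")
  shared %>%
    mutate(z = if (method == "stouffer") {
      .data$z_sum / sqrt(.data$n_signatures)
    } else {
      .data$z_sum / .data$n_signatures
    }) %>%
    select("gene", "z", "n_signatures")
}
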