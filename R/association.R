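#' Mutation-sensitivity association tests on screen AUC values
#'
#' For every gene with non-silent mutations in at least `min_mutants` cell
#' lines (after any cohort exclusion), compares AUC values between mutant
#' and wild-type lines with a two-sample t-test (Welch by default). Genes
#' with fewer mutants, or fewer than `min_wildtype` wild-type lines, are
#' skipped.
#'
#' @param auc Tibble with columns `cell_line, auc`.
#' @param mutations Wide logical tibble: `cell_line` plus one
#'   `TRUE`/`FALSE` column per gene (non-silent mutation present).
#' @param exclude Character vector of gene names; lines mutated in any of
#'   them are removed from the cohort before testing (e.g. `"KRAS"`).
#' @param min_mutants Minimum mutant lines per tested gene (default 4).
#' @param min_wildtype Minimum wild-type lines per tested gene (default 2).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble: `gene, n_mut, n_wt, mean_diff` (mutant minus wild-type
#'   mean AUC), `t, p_value, p_adj_bh`. The Benjamini-Hochberg column is a
#'   convenience addition; the primary readout is the raw t-test.
#' @export
associate_mutations <- function(auc, mutations, exclude = NULL,
                                min_mutants = 4, min_wildtype = 2,
                                var_equal = FALSE) {
  stop_if_missing_cols(auc, c("cell_line", "auc"), "auc")
  stop_if_missing_cols(mutations, "cell_line", "mutations")
  genes <- setdiff(names(mutations), "cell_line")
  if (!all(auc$cell_line %in% mutations$cell_line)) {
    abort("every AUC cell line must appear in the mutation matrix")
  }
  df <- inner_join(auc, mutations, by = "cell_line")
  if (length(exclude) > 0) {
    excl <- intersect(exclude, genes)
    if (length(excl) < length(exclude)) {
      warn(sprintf("exclusion gene(s) not in mutation matrix: %s",
                   paste(setdiff(exclude, genes), collapse = ", ")))
    }
    if (length(excl) > 0) {
      has_any <- Reduce(`|`, lapply(excl, function(g) df[[g]]))
      df <- df[!has_any, , drop = FALSE]
    }
  }
  res <- purrr::map_dfr(genes, function(g) {
    mut <- df$auc[df[[g]]]
    wt <- df$auc[!df[[g]]]
    if (length(mut) < min_mutants || length(wt) < min_wildtype) {
      return(NULL)
    }
    if (sd(mut) == 0 && sd(wt) == 0) {
      # degenerate constant groups: no evidence either way
      return(tibble(gene = g, n_mut = length(mut), n_wt = length(wt),
                    mean_diff = mean(mut) - mean(wt), t = 0, p_value = 1))
    }
    tt <- t.test(mut, wt, var.equal = var_equal)
    tibble(gene = g, n_mut = length(mut), n_wt = length(wt),
           mean_diff = mean(mut) - mean(wt),
           t = unname(tt$statistic), p_value = tt$p.value)
  })
  if (nrow(res) > 0) res$p_adj_bh <- p.adjust(res$p_value, method = "BH")
  res
}

#' Association tests across the standard cohort rules
#'
#' Runs [associate_mutations()] for the three cohorts used with an
#' oncogene-driven screen: the full panel, the panel excluding KRAS-mutant
#' lines, and the panel excluding KRAS- or NRAS-mutant lines. Cohorts whose
#' exclusion genes are absent from the mutation matrix are skipped with a
#' warning.
#'
#' @inheritParams associate_mutations
#' @param cohorts Named list of exclusion gene sets; the default mirrors the
#'   standard rules.
#' @return Bound tibble with a `cohort` column.
#' @export
associate_cohorts <- function(auc, mutations,
                              cohorts = list(
                                all = character(),
                                excl_KRAS = "KRAS",
                                excl_KRAS_NRAS = c("KRAS", "NRAS")),
                              ...) {
  purrr::imap_dfr(cohorts, function(excl, nm) {
    res <- associate_mutations(auc, mutations, exclude = excl, ...)
    if (nrow(res) > 0) res$cohort <- nm
    res
  })
}
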