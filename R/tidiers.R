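#' Tidy a four-parameter logistic fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term, estimate`.
#' @export
tidy.fourpl_fit <- function(x, ...) {
  tibble(term = c("a", "b", "s", "ec50"),
         estimate = c(x$a, x$b, x$s, x$ec50))
}

#' One-row summary of a four-parameter logistic fit
#'
#' @param x A `fourpl_fit`.
#' @param ... Unused.
#' @return Tibble: `auc, ic50, residual_sd, converged,
#'   robust_fallback_used`.
#' @export
glance.fourpl_fit <- function(x, ...) {
  tibble(auc = curve_auc(x), ic50 = curve_ic50(x),
         residual_sd = x$residual_sd, converged = x$converged,
         robust_fallback_used = x$robust_fallback_used)
}

#' Tidy a sigmoid exposure-response fit
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term, estimate`.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble(term = c("ec50", "hill", "bottom"),
         estimate = c(x$ec50, x$hill, x$bottom))
}

#' One-row summary of a sigmoid exposure-response fit
#'
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @return Tibble: `ec50, converged`.
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble(ec50 = x$ec50, converged = x$converged)
}
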