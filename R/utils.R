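# Internal helpers shared across modules.

#' Four-parameter logistic response
#'
#' Evaluates `f(x) = b + (a - b) / (1 + exp(s * log(x / ec50)))`, the
#' dose-response form used throughout the screen: `a` is the upper asymptote
#' (viability of untreated cells), `b` the lower asymptote, `s` the slope
#' (positive `s` gives viability decreasing with dose) and `ec50` the dose of
#' half-maximal effect. The logarithm is natural; any base change is absorbed
#' by `s`.
#'
#' @param x Dose (molar), vector.
#' @param a,b Upper and lower asymptotes (viability fraction).
#' @param s Slope (unitless).
#' @param ec50 Dose of half-maximal effect (same units as `x`), positive.
#' @return Numeric vector of predicted viability fractions.
#' @export
#' @examples
#' fourpl(1e-8, a = 1, b = 0, s = 2, ec50 = 1e-8) # midpoint: 0.5
fourpl <- function(x, a, b, s, ec50) {
  stopifnot(ec50 > 0)
  b + (a - b) / (1 + exp(s * log(x / ec50)))
}

# clip to a closed interval
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# lognormal multiplier with coefficient of variation cv (mean 1)
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# set.seed locally without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}
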