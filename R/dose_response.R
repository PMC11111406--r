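#' Constrained robust four-parameter logistic fit
#'
#' Fits `f(x) = b + (a - b) / (1 + exp(s * log(x / ec50)))` to viability
#' fractions by bounded least squares with the screen's restrictions: the
#' upper asymptote `a` is constrained to \[0.99, 1.01\], the lower asymptote
#' `b` to \[0, 1.01\], curves are not forced to be decreasing, and the
#' optimizer is initialized at a = 1, b = 0.5. When the standard
#' Levenberg-Marquardt fit fails, a robust soft-L1 refit is reported instead
#' and flagged.
#'
#' @param doses Dose vector (molar), at least 4 distinct positive values.
#' @param viability Viability fractions (same length as `doses`).
#' @return An object of class `fourpl_fit`: a list with `a, b, s, ec50`,
#'   `converged`, `robust_fallback_used`, `residual_sd`, and the data range.
#' @seealso [curve_auc()], [curve_ic50()], [tidy.fourpl_fit()]
#' @export
#' @examples
#' d <- 1e-5 / 3^(7:0)
#' fit <- fit_4pl(d, fourpl(d, 1, 0.1, 2, 1e-7))
#' unlist(fit[c("a", "b", "s", "ec50")])
fit_4pl <- function(doses, viability) {
  ok <- is.finite(doses) & is.finite(viability) & doses > 0
  doses <- doses[ok]; viability <- viability[ok]
  if (length(unique(doses)) < 4) {
    abort("fit_4pl needs at least 4 distinct positive doses")
  }
  if (length(viability) == 0 || all(!is.finite(viability))) {
    abort("no usable viability values")
  }
  o <- order(doses)
  doses <- doses[o]; viability <- viability[o]

  # degenerate flat response: construct the flat curve directly
  if (sd(viability) < 1e-12) {
    mv <- mean(viability)
    a <- clip(1, 0.99, 1.01)
    b <- clip(2 * mv - a, 0, 1.01)
    return(new_fourpl(a, b, 0, exp(mean(log(doses))), TRUE, FALSE,
                      0, range(doses)))
  }

  lower <- c(a = 0.99, b = 0, s = -50, log_ec50 = log(min(doses)) - 12)
  upper <- c(a = 1.01, b = 1.01, s = 50, log_ec50 = log(max(doses)) + 12)
  start <- c(a = 1, b = 0.5, s = 1,
             log_ec50 = log(doses[which.min(abs(viability - 0.75))]))
  pred <- function(p) p[2] + (p[1] - p[2]) /
    (1 + exp(p[3] * (log(doses) - p[4])))
  ssr <- function(p) sum((viability - pred(p))^2)

  # stage 1: unconstrained Levenberg-Marquardt; if the optimum already
  # satisfies the asymptote restrictions it is the constrained optimum too
  free <- tryCatch({
    m <- minpack.lm::nlsLM(
      viability ~ b + (a - b) / (1 + exp(s * (log(doses) - log_ec50))),
      start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    list(p = coef(m), conv = m$convInfo$isConv)
  }, error = function(e) NULL)
  tol <- 1e-8
  if (!is.null(free) && free$conv) {
    p <- clip(free$p, lower - tol, upper + tol)  # absorb roundoff only
    if (all(p >= lower - tol & p <= upper + tol) &&
        max(abs(p - free$p)) <= tol) {
      p <- clip(p, lower, upper)
      return(new_fourpl(p[["a"]], p[["b"]], p[["s"]], exp(p[["log_ec50"]]),
                        TRUE, FALSE, sqrt(ssr(p) / length(doses)),
                        range(doses)))
    }
  }

  # stage 2: the free optimum violates a bound (or LM failed): bounded
  # quasi-Newton from the projected free solution and from the standard
  # start, keeping the better of the two
  starts <- list(start)
  if (!is.null(free)) starts <- c(list(clip(free$p, lower, upper)), starts)
  best <- NULL
  for (p0 in starts) {
    op <- tryCatch(
      optim(p0, ssr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (!is.null(best) && best$convergence == 0) {
    p <- clip(best$par, lower, upper)
    return(new_fourpl(p[["a"]], p[["b"]], p[["s"]], exp(p[["log_ec50"]]),
                      TRUE, FALSE, sqrt(best$value / length(doses)),
                      range(doses)))
  }

  # robust fallback: soft-L1 loss, bounded quasi-Newton
  obj <- function(p) {
    r <- viability - pred(p)
    sum(2 * (sqrt(1 + r^2) - 1))
  }
  p0 <- if (!is.null(best)) clip(best$par, lower, upper) else start
  op <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 1000))
  p <- clip(op$par, lower, upper)
  r <- viability - pred(p)
  new_fourpl(p[["a"]], p[["b"]], p[["s"]], exp(p[["log_ec50"]]),
             op$convergence == 0, TRUE, sd(r), range(doses))
}

new_fourpl <- function(a, b, s, ec50, converged, robust, residual_sd,
                       dose_range) {
  structure(list(a = unname(a), b = unname(b), s = unname(s),
                 ec50 = unname(ec50), converged = converged,
                 robust_fallback_used = robust,
                 residual_sd = residual_sd,
                 dose_range = dose_range),
            class = "fourpl_fit")
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf(
    "<fourpl_fit> a=%.3f b=%.3f s=%.3f ec50=%.3g%s%s\n", x$a, x$b, x$s,
    x$ec50, if (!x$converged) " (not converged)" else "",
    if (x$robust_fallback_used) " [robust]" else ""))
  invisible(x)
}

#' Predict viability from a 4PL fit
#' @param object A `fourpl_fit`.
#' @param newdata Dose vector (molar).
#' @param ... Unused.
#' @return Predicted viability fractions.
#' @export
predict.fourpl_fit <- function(object, newdata, ...) {
  fourpl(newdata, object$a, object$b, object$s, object$ec50)
}

#' Area under a fitted dose-response curve
#'
#' Mean fitted viability over the tested log10-dose range:
#' `AUC = (1 / (log10 dmax - log10 dmin)) * integral of f(10^u) du`. A flat
#' curve at full viability gives 1; lower values mean greater sensitivity.
#'
#' @param fit A `fourpl_fit`.
#' @param dose_min,dose_max Integration range (molar); defaults to the
#'   fitted data range.
#' @return AUC (unitless, ~\[0, 1\]).
#' @export
curve_auc <- function(fit, dose_min = NULL, dose_max = NULL) {
  stopifnot(inherits(fit, "fourpl_fit"))
  dose_min <- dose_min %||% fit$dose_range[1]
  dose_max <- dose_max %||% fit$dose_range[2]
  if (!(dose_min > 0 && dose_max > dose_min)) {
    abort("need 0 < dose_min < dose_max")
  }
  u1 <- log10(dose_min); u2 <- log10(dose_max)
  res <- integrate(function(u) predict(fit, 10^u), u1, u2,
                   abs.tol = 1e-9, rel.tol = 1e-9, subdivisions = 500L)
  res$value / (u2 - u1)
}

#' Dose at which a fitted curve crosses 50% viability
#'
#' Closed-form inversion of the logistic. Defined only when the fitted curve
#' drops below 0.5 within the dose range; otherwise `NA`.
#'
#' @param fit A `fourpl_fit`.
#' @param dose_min,dose_max Search range (molar); defaults to the fitted
#'   data range.
#' @return IC50 in molar, or `NA_real_` when the curve never crosses 50%.
#' @export
curve_ic50 <- function(fit, dose_min = NULL, dose_max = NULL) {
  stopifnot(inherits(fit, "fourpl_fit"))
  dose_min <- dose_min %||% fit$dose_range[1]
  dose_max <- dose_max %||% fit$dose_range[2]
  a <- fit$a; b <- fit$b; s <- fit$s
  f1 <- predict(fit, dose_min); f2 <- predict(fit, dose_max)
  if (min(f1, f2) >= 0.5) return(NA_real_)
  if (s == 0 || a == b) return(NA_real_)
  t <- (a - 0.5) / (0.5 - b)
  if (!is.finite(t) || t <= 0) return(NA_real_)
  x <- fit$ec50 * exp(log(t) / s)
  if (x < dose_min || x > dose_max) return(NA_real_)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit dose-response curves for every cell line of a screen profile
#'
#' Tidy wrapper around [fit_4pl()], [curve_auc()] and [curve_ic50()]:
#' takes a collapsed treatment-level profile and returns one row per cell
#' line.
#'
#' @param profile Tibble with columns `cell_line, dose_molar, viability`
#'   (e.g. `process_screen(...)$profile`).
#' @return Tibble: `cell_line, a, b, s, ec50, auc, ic50, converged,
#'   robust_fallback_used`.
#' @export
fit_dose_response <- function(profile) {
  stop_if_missing_cols(profile, c("cell_line", "dose_molar", "viability"),
                       "profile")
  profile %>%
    group_by(.data$cell_line) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_4pl(df$dose_molar, df$viability)
      tibble(a = fit$a, b = fit$b, s = fit$s, ec50 = fit$ec50,
             auc = curve_auc(fit), ic50 = curve_ic50(fit),
             converged = fit$converged,
             robust_fallback_used = fit$robust_fallback_used)
    }) %>%
    ungroup()
}

#' Three-parameter sigmoidal exposure-response fit
#'
#' Fits `r(C) = bottom + (1 - bottom) / (1 + (C / ec50)^h)` to
#' vehicle-normalized responses, with the top fixed at 1 (the
#' three-parameter convention for vehicle-normalized data); `bottom` is
#' bounded to \[0, 1\], `h > 0`. Used to derive pharmacodynamic EC50 values
#' from concentration-response data.
#'
#' @param concentrations Concentrations (nM), positive.
#' @param responses Responses as fraction of vehicle.
#' @return An object of class `sigmoid_fit`: list with `ec50, hill, bottom,
#'   converged`.
#' @export
fit_sigmoid_ec50 <- function(concentrations, responses) {
  ok <- is.finite(concentrations) & is.finite(responses)
  concentrations <- concentrations[ok]; responses <- responses[ok]
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (length(concentrations) < 4 ||
      diff(range(log10(concentrations))) < 1) {
    abort("need >= 4 points spanning at least one log of concentration")
  }
  if (sd(responses) < 1e-10) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_,
                          bottom = mean(responses), converged = FALSE),
                     class = "sigmoid_fit"))
  }
  lower <- c(bottom = 0, log_ec50 = log(min(concentrations)) - 12,
             h = 1e-3)
  upper <- c(bottom = 1, log_ec50 = log(max(concentrations)) + 12, h = 20)
  start <- c(bottom = 0.05,
             log_ec50 = log(concentrations[which.min(abs(responses - 0.5))]),
             h = 1)
  pred <- function(p) p[1] + (1 - p[1]) /
    (1 + exp(p[3] * (log(concentrations) - p[2])))
  ssr <- function(p) sum((responses - pred(p))^2)
  as_fit <- function(p, conv) {
    structure(list(ec50 = exp(p[["log_ec50"]]), hill = p[["h"]],
                   bottom = p[["bottom"]], converged = conv),
              class = "sigmoid_fit")
  }

  # unconstrained fit first; accept it when it satisfies the restrictions,
  # otherwise refit by bounded quasi-Newton from the projected solution
  free <- tryCatch({
    m <- minpack.lm::nlsLM(
      responses ~ bottom + (1 - bottom) /
        (1 + exp(h * (log(concentrations) - log_ec50))),
      start = as.list(start),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    list(p = coef(m), conv = m$convInfo$isConv)
  }, error = function(e) NULL)
  tol <- 1e-8
  if (!is.null(free) && free$conv &&
      all(free$p >= lower - tol & free$p <= upper + tol)) {
    return(as_fit(clip(free$p, lower, upper), TRUE))
  }
  starts <- list(start)
  if (!is.null(free)) starts <- c(list(clip(free$p, lower, upper)), starts)
  best <- NULL
  for (p0 in starts) {
    op <- tryCatch(
      optim(p0, ssr, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) {
    return(structure(list(ec50 = NA_real_, hill = NA_real_,
                          bottom = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }
  as_fit(clip(best$par, lower, upper), best$convergence == 0)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> ec50=%.4g hill=%.3f bottom=%.3f%s\n",
              x$ec50, x$hill, x$bottom,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Predict response from a sigmoid exposure-response fit
#' @param object A `sigmoid_fit`.
#' @param newdata Concentration vector.
#' @param ... Unused.
#' @export
predict.sigmoid_fit <- function(object, newdata, ...) {
  object$bottom + (1 - object$bottom) /
    (1 + (newdata / object$ec50)^object$hill)
}
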