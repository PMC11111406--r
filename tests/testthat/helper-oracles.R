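# Independent brute-force oracles used to check the package implementations.

# minimal misclassification error of a single threshold classifier
# (below threshold -> positive), scanning every threshold position
# exhaustively including both open/closed sides of each observed value
oracle_threshold_error <- function(neg, pos) {
  cand <- c(-Inf, Inf, sort(unique(c(neg, pos))),
            sort(unique(c(neg, pos))) + 1e-9,
            sort(unique(c(neg, pos))) - 1e-9)
  n <- length(neg) + length(pos)
  min(vapply(cand, function(t) {
    (sum(neg < t) + sum(pos >= t)) / n
  }, numeric(1)))
}

# sorted-middle median
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# exhaustive maximization of the circular two-sample t statistic
oracle_cbs_split <- function(x) {
  m <- length(x)
  best <- list(t = -1, i = 0, j = 1)
  for (i in 0:(m - 1)) {
    for (j in (i + 1):m) {
      if (i == 0 && j == m) next
      arc <- x[(i + 1):j]
      rest <- x[-((i + 1):j)]
      n1 <- length(arc); n2 <- length(rest)
      m1 <- mean(arc); m2 <- mean(rest)
      if (abs(m1 - m2) < 1e-12) next
      within <- sum((arc - m1)^2) + sum((rest - m2)^2)
      s2 <- within / (m - 2)
      t <- if (s2 <= 1e-24) 1e12 else
        abs(m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# the circular split statistic at a given breakpoint pair
oracle_cbs_stat <- function(x, i, j) {
  m <- length(x)
  arc <- x[(i + 1):j]
  rest <- x[-((i + 1):j)]
  m1 <- mean(arc); m2 <- mean(rest)
  if (abs(m1 - m2) < 1e-12) return(0)
  within <- sum((arc - m1)^2) + sum((rest - m2)^2)
  s2 <- within / (m - 2)
  if (s2 <= 1e-24) return(1e12)
  abs(m1 - m2) / sqrt(s2 * (1 / length(arc) + 1 / length(rest)))
}

# two-sided Fisher p by direct enumeration of all tables with fixed margins
oracle_fisher_two_sided <- function(k1, n1, k2, n2) {
  K <- k1 + k2
  xs <- max(0, K - n2):min(K, n1)
  dens <- vapply(xs, function(x) {
    choose(n1, x) * choose(n2, K - x) / choose(n1 + n2, K)
  }, numeric(1))
  d_obs <- dens[xs == k1]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

# quadratic scan for half-open interval overlap
oracle_overlaps <- function(ev_start, ev_end, g_start, g_end) {
  which(g_start < ev_end & ev_start < g_end)
}

# default dose series used throughout the tests
test_doses <- function() 1e-5 / 3^(7:0)

# viability observations for one line under multiplicative lognormal noise,
# collapsed to the median across replicates
simulate_line_profile <- function(doses, a, b, s, ec50, cv, n_rep = 3) {
  v <- rep(fourpl(doses, a, b, s, ec50), each = n_rep)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    v <- v * exp(rnorm(length(v), -sdlog^2 / 2, sdlog))
  }
  data.frame(dose_molar = rep(doses, each = n_rep), viability = v) |>
    dplyr::group_by(dose_molar) |>
    dplyr::summarise(viability = median(viability), .groups = "drop")
}

# numeric AUC of a known 4PL over a log10-dose range (quadrature oracle)
oracle_auc <- function(a, b, s, ec50, dmin, dmax) {
  integrate(function(u) fourpl(10^u, a, b, s, ec50),
            log10(dmin), log10(dmax), rel.tol = 1e-10)$value /
    (log10(dmax) - log10(dmin))
}
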