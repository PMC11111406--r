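test_that("noiseless 4PL data are recovered within 1%", {
  d <- test_doses()
  fit <- fit_4pl(d, fourpl(d, 1, 0.1, 2, 1e-8))
  expect_equal(fit$a, 1, tolerance = 0.01)
  expect_equal(fit$b, 0.1, tolerance = 0.01)
  expect_equal(fit$s, 2, tolerance = 0.01)
  expect_equal(fit$ec50, 1e-8, tolerance = 0.01)
  expect_true(fit$converged)
  expect_false(fit$robust_fallback_used)
})

test_that("flat full-viability data give a flat curve with AUC 1", {
  d <- test_doses()
  fit <- fit_4pl(d, rep(1, 8))
  expect_equal(predict(fit, d), rep(1, 8), tolerance = 1e-8)
  expect_equal(curve_auc(fit), 1, tolerance = 1e-6)
})

test_that("asymptote bounds are always honored and fits are order-invariant", {
  set.seed(17)
  d <- test_doses()
  for (i in 1:25) {
    v <- pmin(pmax(fourpl(d, 1, runif(1, 0, 0.5), runif(1, 0.5, 3),
                          10^runif(1, -8.5, -6)) *
                     exp(rnorm(8, 0, 0.15)), 0), 1.2)
    fit <- fit_4pl(d, v)
    expect_gte(fit$a, 0.99); expect_lte(fit$a, 1.01)
    expect_gte(fit$b, 0);    expect_lte(fit$b, 1.01)
    o <- sample(8)
    fit2 <- fit_4pl(d[o], v[o])
    expect_lt(abs(fit$ec50 - fit2$ec50) / fit$ec50, 1e-6)
    expect_lt(abs(fit$b - fit2$b), 1e-6)
  }
})

test_that("curve AUC matches quadrature and is monotone in the curve", {
  d <- test_doses()
  flat05 <- fit_4pl(d, rep(0.5, 8))
  expect_equal(curve_auc(flat05), 0.5, tolerance = 1e-6)

  fit <- fit_4pl(d, fourpl(d, 1, 0, 2, 1e-7))
  expect_equal(curve_auc(fit),
               oracle_auc(fit$a, fit$b, fit$s, fit$ec50, min(d), max(d)),
               tolerance = 1e-6)

  # steep curve centred in the log-dose range tends to the step limit 0.5
  centre <- 10^mean(log10(range(d)))
  steep <- fit_4pl(d, fourpl(d, 1, 0, 25, centre))
  expect_equal(curve_auc(steep), 0.5, tolerance = 0.02)

  # pointwise-lower curve has lower AUC
  hi <- fit_4pl(d, fourpl(d, 1, 0.4, 2, 1e-7))
  lo <- fit_4pl(d, fourpl(d, 1, 0.05, 2, 1e-7))
  expect_lt(curve_auc(lo), curve_auc(hi))

  expect_error(curve_auc(fit, 1e-6, 1e-8), "dose_min")
})

test_that("IC50 inverts the logistic exactly and is NA when undefined", {
  d <- test_doses()
  # symmetric curve (a = 1, b = 0): the 50% crossing is the EC50 itself
  sym <- structure(list(a = 1, b = 0, s = 2, ec50 = 1e-8,
                        dose_range = range(d)), class = "fourpl_fit")
  expect_identical(curve_ic50(sym), 1e-8)
  fit <- fit_4pl(d, fourpl(d, 1, 0, 2, 1e-8))
  expect_equal(curve_ic50(fit), fit$ec50, tolerance = 1e-6)

  shallow <- fit_4pl(d, fourpl(d, 1, 0.6, 2, 1e-8))
  expect_true(is.na(curve_ic50(shallow)))

  fit2 <- fit_4pl(d, fourpl(d, 1, 0.2, 1, 1e-8))
  ic <- curve_ic50(fit2)
  expect_lt(abs(predict(fit2, ic) - 0.5), 1e-9)
  # bisection oracle
  bis <- uniroot(function(x) predict(fit2, x) - 0.5,
                 c(min(d), max(d)), tol = 1e-15)$root
  expect_equal(ic, bis, tolerance = 1e-6)
})

test_that("the logistic midpoint identity holds for any slope", {
  for (s in c(0.5, 1, 3, -2)) {
    expect_equal(fourpl(1e-8, 1, 0.2, s, 1e-8), 0.6)
  }
})

test_that("tidy and glance summarize a fit", {
  d <- test_doses()
  fit <- fit_4pl(d, fourpl(d, 1, 0.1, 2, 1e-8))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b", "s", "ec50"))
  gl <- glance(fit)
  expect_true(all(c("auc", "ic50", "converged") %in% names(gl)))
})

test_that("three-parameter sigmoid recovers the EC50 and flags flat data", {
  conc <- 10^seq(0, 4, length.out = 12)
  r <- 1 / (1 + (conc / 142)^1.5)
  fit <- fit_sigmoid_ec50(conc, r)
  expect_equal(fit$ec50, 142, tolerance = 0.01)
  expect_equal(predict(fit, fit$ec50), (1 + fit$bottom) / 2,
               tolerance = 1e-6)

  flat <- fit_sigmoid_ec50(conc, rep(1, 12))
  expect_false(flat$converged)
  expect_true(is.na(flat$ec50))
  expect_error(fit_sigmoid_ec50(c(-1, 1, 10, 100), rep(0.5, 4)), "positive")
})

test_that("exposure metrics: trapezoid AUC, terminal half-life, Kp", {
  em <- exposure_metrics(data.frame(time = 0:48, conc = 10))
  expect_equal(em$auc, 480)

  two <- rbind(data.frame(tissue = "blood", time = 0:24,
                          conc = 100 * exp(-0.3 * (0:24))),
               data.frame(tissue = "tumour", time = 0:24,
                          conc = 100 * exp(-0.3 * (0:24))))
  em2 <- exposure_metrics(two)
  expect_equal(em2$kp, c(1, 1))

  k <- log(2) / 3.5
  dec <- data.frame(time = seq(0, 24, 0.5),
                    conc = 50 * exp(-k * seq(0, 24, 0.5)))
  expect_equal(exposure_metrics(dec)$half_life, 3.5, tolerance = 0.01)
  expect_error(exposure_metrics(data.frame(time = c(2, 1), conc = 1:2)),
               "sorted")
})

test_that("tumour response metrics match their definitions", {
  d <- data.frame(tumour_id = "t1", time = c(0, 7), volume = c(100, 200))
  r <- tumour_response(d)
  expect_equal(r$best_response, 0)  # best (minimum) change is baseline 0
  expect_equal(max(r$timecourse[[1]]$pct_change), 100)

  const <- data.frame(tumour_id = "t2", time = 0:4, volume = 150)
  r2 <- tumour_response(const)
  expect_equal(r2$growth_rate, 0)
  expect_equal(r2$best_response, 0)

  tt <- seq(0, 8, 2)
  expo <- data.frame(tumour_id = "t3", time = tt,
                     volume = 120 * exp(0.1 * tt))
  expect_equal(tumour_response(expo)$growth_rate, 0.1, tolerance = 1e-6)

  shrink <- data.frame(tumour_id = "t4", time = c(0, 3, 6),
                       volume = c(100, 60, 80))
  expect_equal(tumour_response(shrink)$best_response, -40)
})
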