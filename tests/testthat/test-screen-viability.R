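test_that("log-viability is zero at the negative-control median and -1 at half", {
  cal <- tibble::tibble(
    plate_id = "p1", well = c("N1", "N2", "N3", "T1", "T2"),
    treatment = c(rep("negative_control", 3), "treatment", "treatment"),
    dose_molar = c(0, 0, 0, 1e-7, 1e-8),
    batch = 1, pool = 1, replicate = 1,
    barcode_id = "A", barcode_class = "cell",
    corrected_log2_mfi = c(10, 10.2, 9.8, 10, 9))
  lv <- compute_log_viability(cal)
  expect_equal(lv$log_viability[lv$dose_molar == 1e-7], 0)   # x = mu_minus
  expect_equal(lv$log_viability[lv$dose_molar == 1e-8], -1)  # halved signal
})

test_that("replicate collapse is the median", {
  v <- tibble::tibble(cell_line = "A", dose_molar = 1e-8,
                      log_viability = c(-1.0, -1.2, -3.0))
  expect_equal(collapse_replicates(v)$log_viability, -1.2)
  v1 <- v[1, ]
  expect_equal(collapse_replicates(v1)$log_viability, -1.0)
  set.seed(3)
  vr <- tibble::tibble(cell_line = "A", dose_molar = 1e-8,
                       log_viability = rnorm(7))
  expect_equal(collapse_replicates(vr)$log_viability,
               oracle_median(vr$log_viability))
})

test_that("single-batch matrices pass through batch correction unchanged", {
  set.seed(8)
  m <- matrix(rnorm(80), nrow = 8)
  expect_equal(correct_batch_effects(m, rep(1, 10)), m, tolerance = 1e-10)
})

test_that("additive and multiplicative batch effects are removed", {
  set.seed(9)
  base <- matrix(rnorm(8 * 60, mean = -1, sd = 0.1), nrow = 8)
  batch <- rep(c(1, 2), each = 30)
  m <- base
  m[, batch == 2] <- m[, batch == 2] + 0.8          # additive offset
  corr <- correct_batch_effects(m, batch)
  d <- rowMeans(corr[, batch == 2]) - rowMeans(corr[, batch == 1])
  expect_lt(max(abs(d)), 0.05)

  m2 <- base
  m2[, batch == 2] <- rowMeans(base[, batch == 2]) +
    2 * (m2[, batch == 2] - rowMeans(base[, batch == 2]))  # 2x scale
  corr2 <- correct_batch_effects(m2, batch)
  v1 <- apply(corr2[, batch == 1], 1, var)
  v2 <- apply(corr2[, batch == 2], 1, var)
  expect_lt(abs(mean(v2) / mean(v1) - 1), 0.1)
})

test_that("processing a noiseless screen recovers true viabilities exactly", {
  truth <- tibble::tibble(cell_line = sprintf("L%d", 1:6), a = 1,
                          b = seq(0, 0.3, length.out = 6),
                          s = seq(1, 2.5, length.out = 6),
                          ec50 = 10^seq(-8, -6.5, length.out = 6))
  sim <- simulate_screen(screen_sim_config(
    n_cell_lines = 6, n_pools = 1, n_batches = 1, true_params = truth,
    noise_cv = 0, well_slope_sd = 0, seed = 31))  # well offsets on, noise off
  res <- process_screen(sim$plates)
  expected <- tidyr::expand_grid(i = 1:6, dose_molar = sim$config$doses) |>
    dplyr::mutate(cell_line = truth$cell_line[i],
                  v = fourpl(dose_molar, truth$a[i], truth$b[i],
                             truth$s[i], truth$ec50[i]))
  cmp <- dplyr::inner_join(res$profile, expected,
                           by = c("cell_line", "dose_molar"))
  expect_equal(nrow(cmp), 48)
  expect_lt(max(abs(cmp$viability - cmp$v)), 1e-6)
})

test_that("pool-keyed batch offsets are corrected end to end", {
  sim <- simulate_screen(screen_sim_config(
    n_cell_lines = 40, n_pools = 4, n_batches = 2,
    noise_cv = 0, batch_shift = c(0, 0.8), seed = 32))
  res <- process_screen(sim$plates)
  post <- res$corrected |>
    dplyr::group_by(batch, dose_molar) |>
    dplyr::summarise(m = mean(log_viability), .groups = "drop") |>
    tidyr::pivot_wider(names_from = batch, values_from = m)
  expect_lt(max(abs(post$`2` - post$`1`)), 0.05)
})
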