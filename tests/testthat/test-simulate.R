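test_that("noiseless generator reproduces the true logistic exactly", {
  truth <- tibble::tibble(cell_line = c("A", "B"), a = 1, b = c(0, 0.2),
                          s = c(2, 1), ec50 = c(1e-8, 1e-7))
  sim <- simulate_screen(screen_sim_config(
    n_cell_lines = 2, n_pools = 1, n_batches = 1, true_params = truth,
    noise_cv = 0, well_effect_sd = 0, well_slope_sd = 0, seed = 1))
  # measured viability = mfi / (median negative-control mfi) per line
  pl <- sim$plates |> dplyr::filter(barcode_class == "cell")
  base <- pl |> dplyr::filter(treatment == "negative_control") |>
    dplyr::group_by(barcode_id, plate_id) |>
    dplyr::summarise(mu = median(mfi), .groups = "drop")
  tr <- pl |> dplyr::filter(treatment == "treatment") |>
    dplyr::inner_join(base, by = c("barcode_id", "plate_id")) |>
    dplyr::mutate(v = mfi / mu)
  expected <- fourpl(tr$dose_molar,
                     truth$a[match(tr$barcode_id, truth$cell_line)],
                     truth$b[match(tr$barcode_id, truth$cell_line)],
                     truth$s[match(tr$barcode_id, truth$cell_line)],
                     truth$ec50[match(tr$barcode_id, truth$cell_line)])
  expect_equal(tr$v, expected, tolerance = 1e-12)
  # logistic midpoint: viability 0.5 at the EC50 dose
  expect_equal(fourpl(1e-8, 1, 0, 3, 1e-8), 0.5)
})

test_that("screen generator is deterministic and validates its config", {
  cfg <- screen_sim_config(n_cell_lines = 4, n_pools = 1, seed = 99)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$plates, s2$plates)
  expect_identical(s1$truth, s2$truth)
  expect_error(screen_sim_config(spike_in_levels = rep(1, 10)),
               "increasing")
  expect_error(screen_sim_config(n_replicates = 0), "n_replicates")
})

test_that("spike-ins are identical across wells before distortion", {
  sim <- simulate_screen(screen_sim_config(
    n_cell_lines = 4, n_pools = 1, n_batches = 1, noise_cv = 0,
    well_effect_sd = 0, well_slope_sd = 0, seed = 2))
  sp <- sim$plates |> dplyr::filter(barcode_class == "spike") |>
    dplyr::group_by(barcode_id) |>
    dplyr::summarise(nvals = dplyr::n_distinct(round(log2_mfi, 9)))
  expect_true(all(sp$nvals == 1))
})

test_that("cnv generator gives Poisson counts with the implanted structure", {
  cfg <- cnv_sim_config(n_bins = 1000, mean_depth = 100, seed = 3)
  sim <- simulate_cnv_sample(cfg)
  expect_true(abs(mean(sim$bins$count) - 100) < 3 * sqrt(100 / 1000))
  expect_true(all(sim$bins$count >= 0))
  expect_true(all(sim$bins$count == floor(sim$bins$count)))

  ev <- tibble::tibble(start_bin = 100L, end_bin = 110L, copy_ratio = 2)
  sim2 <- simulate_cnv_sample(cnv_sim_config(n_bins = 1000, mean_depth = 100,
                                             events = ev, seed = 4))
  inside <- mean(sim2$bins$count[101:110])
  outside <- mean(sim2$bins$count[-(101:110)])
  expect_equal(inside / outside, 2, tolerance = 0.25)
  expect_equal(nrow(sim2$true_segments), 3)

  # injected GC bias induces a detectable count-GC correlation
  sim3 <- simulate_cnv_sample(cnv_sim_config(n_bins = 2000, mean_depth = 500,
                                             gc_bias_amplitude = 0.2,
                                             seed = 5))
  ct <- cor.test(sim3$bins$count, sim3$bins$gc)
  expect_lt(ct$p.value, 1e-6)

  expect_error(cnv_sim_config(mean_depth = -1), "positive")
  expect_error(cnv_sim_config(n_bins = 100,
                              events = tibble::tibble(start_bin = 90L,
                                                      end_bin = 120L,
                                                      copy_ratio = 2)))
})

test_that("dose-matrix generator injects a recoverable interaction", {
  doses <- 10^(-8:-6)
  m0 <- simulate_dose_matrix(doses, doses, c(0.1, 0.4, 0.7),
                             c(0.2, 0.5, 0.8), interaction = 0, noise_cv = 0)
  expect_equal(max(abs(bliss_excess(m0)$excess)), 0, tolerance = 1e-12)

  inter <- matrix(0, 3, 3); inter[2, 2] <- 0.2
  m1 <- simulate_dose_matrix(doses, doses, c(0.1, 0.4, 0.7),
                             c(0.2, 0.5, 0.8), interaction = inter,
                             noise_cv = 0)
  e <- bliss_excess(m1)
  at <- e$excess[e$dose_a == doses[2] & e$dose_b == doses[2]]
  expect_equal(at, 0.2, tolerance = 1e-12)
  expect_equal(sum(abs(e$excess) > 1e-12), 1)

  expect_error(simulate_dose_matrix(doses, doses, c(0.1, 0.4, 1.2),
                                    c(0.2, 0.5, 0.8)), "\\[0, 1\\]")
})

test_that("pk-pd generator follows the one-compartment and sigmoid forms", {
  expect_equal(pk_concentration(0, 10, 1.2, 0.2, 1), 0)
  # ka == ke degenerate case stays finite and positive
  expect_gt(pk_concentration(2, 10, 0.5, 0.5, 1), 0)
  pk <- simulate_pkpd(doses = 25, times = c(0, 1, 4, 8, 24), ec50_pd = 142,
                      hill = 1.5)
  expect_equal(pk$response$response[pk$response$time == 0], 1)
  # response is 0.5 where concentration equals the PD EC50
  r <- 1 / (1 + (142 / 142)^1.5)
  expect_equal(r, 0.5)
  # dense noiseless sampling and refit recovers the PD EC50 within 1%
  pk2 <- simulate_pkpd(doses = c(10, 25, 50), times = seq(0.25, 48, 0.25),
                       ec50_pd = 142, hill = 1.5)
  fit <- fit_sigmoid_ec50(pk2$response$conc, pk2$response$response)
  expect_equal(fit$ec50, 142, tolerance = 0.01)
})
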