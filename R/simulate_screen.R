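#' Configuration for a simulated pooled-barcode viability screen
#'
#' Builds the parameter set for [simulate_screen()]. The defaults emulate the
#' design of a multiplexed barcoded cell-line screen: pools of barcoded lines
#' seeded into 384-well plates, an 8-point threefold dilution series in
#' triplicate, ten spike-in control barcodes at fixed increasing abundances in
#' every well, vehicle (negative-control) and lethal (positive-control) wells
#' on every plate, multiplicative lognormal measurement noise on linear MFI
#' (so additive Gaussian noise on log2 MFI), per-well affine detection
#' distortions that the spike-in calibration is designed to remove, and
#' additive/multiplicative batch effects on log-viability keyed to pools.
#'
#' @param n_cell_lines Number of cell-line barcodes across all pools.
#' @param n_pools Number of pools; lines are split evenly across pools.
#' @param n_batches Number of batches; pools are assigned round-robin.
#' @param spike_in_levels Ten strictly increasing linear-MFI abundances for
#'   the spike-in control barcodes.
#' @param true_params Optional tibble with columns `cell_line, a, b, s, ec50`
#'   giving each line's true four-parameter logistic response. When `NULL`,
#'   parameters are drawn at random (a = 1, b ~ U(0, 0.35), s ~ U(0.8, 2.5),
#'   ec50 ~ 10^U(-8, -6) molar) so curves fall inside the dose range.
#' @param doses Dose series in molar; default 8-point threefold dilution from
#'   10 uM.
#' @param n_replicates Replicate plates per pool (default 3).
#' @param noise_cv Lognormal coefficient of variation of the MFI readout.
#' @param batch_shift Additive log2 log-viability offset per batch (length
#'   `n_batches`, recycled), applied to cell barcodes in treatment wells.
#' @param batch_scale Multiplicative factor on treated log-viability per
#'   batch (length `n_batches`, recycled).
#' @param well_effect_sd SD (log2 units) of the per-well additive detection
#'   offset; 0 disables well effects.
#' @param well_slope_sd SD of log per-well detection gain (slope of the
#'   affine distortion); 0 gives pure shifts.
#' @param n_neg_wells,n_pos_wells Negative-/positive-control wells per plate.
#' @param pos_control_viability Viability assigned to positive-control
#'   (lethal) wells; kept slightly above 0 so log-viability stays finite.
#' @param seed Optional RNG seed; identical seed and config give identical
#'   output.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_cell_lines = 40,
                              n_pools = 2,
                              n_batches = 2,
                              spike_in_levels = 2^seq(6, 13, length.out = 10),
                              true_params = NULL,
                              doses = 1e-5 / 3^(7:0),
                              n_replicates = 3,
                              noise_cv = 0.1,
                              batch_shift = 0,
                              batch_scale = 1,
                              well_effect_sd = 0.3,
                              well_slope_sd = 0.05,
                              n_neg_wells = 6,
                              n_pos_wells = 4,
                              pos_control_viability = 0.05,
                              seed = NULL) {
  if (length(spike_in_levels) != 10 || any(diff(spike_in_levels) <= 0)) {
    abort("spike_in_levels must be 10 strictly increasing abundances")
  }
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  d <- sort(doses)
  if (any(d <= 0) || any(diff(d) <= 0)) {
    abort("doses must be positive and distinct")
  }
  if (!is.null(true_params)) {
    stop_if_missing_cols(true_params, c("cell_line", "a", "b", "s", "ec50"),
                         "true_params")
    if (any(true_params$ec50 <= 0)) abort("true ec50 must be positive")
  }
  structure(list(
    n_cell_lines = n_cell_lines, n_pools = n_pools, n_batches = n_batches,
    spike_in_levels = spike_in_levels, true_params = true_params,
    doses = doses, n_replicates = n_replicates, noise_cv = noise_cv,
    batch_shift = rep_len(batch_shift, n_batches),
    batch_scale = rep_len(batch_scale, n_batches),
    well_effect_sd = well_effect_sd, well_slope_sd = well_slope_sd,
    n_neg_wells = n_neg_wells, n_pos_wells = n_pos_wells,
    pos_control_viability = pos_control_viability, seed = seed
  ), class = "screen_sim_config")
}

# numeric AUC of a true 4PL over the tested log10-dose range (generator-side
# arithmetic on known parameters, independent of the fitting module)
true_curve_auc <- function(a, b, s, ec50, dose_min, dose_max) {
  u <- seq(log10(dose_min), log10(dose_max), length.out = 2001)
  f <- fourpl(10^u, a, b, s, ec50)
  pracma::trapz(u, f) / (log10(dose_max) - log10(dose_min))
}

#' Simulate a pooled-barcode viability screen
#'
#' Generates a plate-level MFI table plus a ground-truth table. Each plate
#' (one per pool x replicate) carries one treatment well per dose, vehicle
#' wells and lethal wells; every well contains the ten spike-in barcodes and
#' the pool's cell-line barcodes. Expected cell-barcode signal at dose d is
#' `baseline * f(d)` where `f` is the line's true four-parameter logistic
#' curve; spike-ins are identical in expectation across wells before the
#' per-well distortion. With `noise_cv = 0`, `batch_shift = 0` and
#' `well_effect_sd = 0` the measured viability equals the true curve exactly.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements
#'   \describe{
#'     \item{plates}{tibble: plate_id, well, batch, pool, treatment
#'       (`treatment` / `negative_control` / `positive_control`), dose_molar,
#'       replicate, barcode_id, barcode_class (`spike`/`cell`), mfi, log2_mfi}
#'     \item{truth}{tibble: cell_line, pool, batch, baseline_log2_mfi,
#'       a, b, s, ec50, auc}
#'     \item{config}{the input configuration}
#'   }
#' @export
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_cell_lines = 4, n_pools = 1,
#'   n_batches = 1, noise_cv = 0, well_effect_sd = 0, seed = 1))
#' head(sim$plates)
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  with_seed(config$seed, {
    cfg <- config
    lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
    pool_of <- rep_len(seq_len(cfg$n_pools), cfg$n_cell_lines)
    pool_of <- sort(pool_of)
    batch_of_pool <- rep_len(seq_len(cfg$n_batches), cfg$n_pools)

    if (is.null(cfg$true_params)) {
      truth <- tibble(
        cell_line = lines,
        a = 1,
        b = runif(cfg$n_cell_lines, 0, 0.35),
        s = runif(cfg$n_cell_lines, 0.8, 2.5),
        ec50 = 10^runif(cfg$n_cell_lines, -8, -6)
      )
    } else {
      truth <- as_tibble(cfg$true_params)[, c("cell_line", "a", "b", "s", "ec50")]
      truth <- truth[seq_len(min(nrow(truth), cfg$n_cell_lines)), ]
      lines <- truth$cell_line
      cfg$n_cell_lines <- nrow(truth)
      pool_of <- sort(rep_len(seq_len(cfg$n_pools), cfg$n_cell_lines))
    }
    truth$pool <- pool_of
    truth$batch <- batch_of_pool[pool_of]
    truth$baseline_log2_mfi <- runif(cfg$n_cell_lines, 9, 12)
    dmin <- min(cfg$doses); dmax <- max(cfg$doses)
    truth$auc <- purrr::pmap_dbl(
      truth[, c("a", "b", "s", "ec50")],
      function(a, b, s, ec50) true_curve_auc(a, b, s, ec50, dmin, dmax)
    )

    spike_log2 <- log2(cfg$spike_in_levels)
    pivot <- mean(spike_log2)
    sd_log2 <- if (cfg$noise_cv > 0) sqrt(log(1 + cfg$noise_cv^2)) / log(2) else 0

    # well plan per plate
    well_plan <- bind_rows(
      tibble(well = sprintf("T%02d", seq_along(cfg$doses)),
             treatment = "treatment", dose_molar = sort(cfg$doses, decreasing = TRUE)),
      tibble(well = sprintf("N%02d", seq_len(cfg$n_neg_wells)),
             treatment = "negative_control", dose_molar = 0),
      tibble(well = sprintf("P%02d", seq_len(cfg$n_pos_wells)),
             treatment = "positive_control", dose_molar = 0)
    )

    plate_rows <- list()
    k <- 1L
    for (pool in seq_len(cfg$n_pools)) {
      batch <- batch_of_pool[pool]
      pool_truth <- truth[truth$pool == pool, ]
      for (rep_i in seq_len(cfg$n_replicates)) {
        plate_id <- sprintf("pool%02d_rep%d", pool, rep_i)
        for (w in seq_len(nrow(well_plan))) {
          wp <- well_plan[w, ]
          offset <- if (cfg$well_effect_sd > 0) rnorm(1, 0, cfg$well_effect_sd) else 0
          slope <- if (cfg$well_slope_sd > 0) exp(rnorm(1, 0, cfg$well_slope_sd)) else 1
          distort <- function(x) pivot + offset + slope * (x - pivot)

          # true log2 signal per barcode
          if (wp$treatment == "treatment") {
            v <- fourpl(wp$dose_molar, pool_truth$a, pool_truth$b,
                        pool_truth$s, pool_truth$ec50)
            lv <- cfg$batch_scale[batch] * log2(v) + cfg$batch_shift[batch]
          } else if (wp$treatment == "negative_control") {
            lv <- rep(0, nrow(pool_truth))
          } else {
            lv <- rep(log2(cfg$pos_control_viability), nrow(pool_truth))
          }
          cell_log2 <- pool_truth$baseline_log2_mfi + lv
          base_log2 <- c(spike_log2, cell_log2)
          noise <- if (sd_log2 > 0) rnorm(length(base_log2), 0, sd_log2) else 0
          obs_log2 <- distort(base_log2) + noise

          plate_rows[[k]] <- tibble(
            plate_id = plate_id, well = wp$well, batch = batch, pool = pool,
            treatment = wp$treatment, dose_molar = wp$dose_molar,
            replicate = rep_i,
            barcode_id = c(sprintf("SPIKE%02d", 1:10), pool_truth$cell_line),
            barcode_class = c(rep("spike", 10), rep("cell", nrow(pool_truth))),
            log2_mfi = obs_log2,
            mfi = 2^obs_log2
          )
          k <- k + 1L
        }
      }
    }
    structure(list(plates = bind_rows(plate_rows), truth = truth,
                   config = cfg),
              class = "screen_sim")
  })
}
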