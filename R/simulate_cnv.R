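#' Configuration for a simulated sparse whole-genome copy-number sample
#'
#' Emulates the input of sparse whole-genome sequencing: uniquely mapped
#' reads counted in fixed-width genomic bins. Defaults use a single synthetic
#' chromosome of 2,000 bins of 100 kb at a mean depth of 150 reads per bin
#' (roughly 3 million reads over a 20,000-bin genome); `paper_scale = TRUE`
#' switches to 20,000 bins.
#'
#' @param n_bins Number of bins (default 2,000).
#' @param bin_width Bin width in bp (default 1e5).
#' @param gc Optional per-bin GC fraction in (0, 1); default a smooth
#'   sinusoidal profile with mild jitter, clipped to \[0.3, 0.62\].
#' @param events Tibble of `start_bin, end_bin, copy_ratio` (0-based
#'   half-open bin indices) describing implanted gains/losses; empty for a
#'   flat genome.
#' @param mean_depth Expected reads per diploid bin (> 0).
#' @param gc_bias_amplitude Amplitude of a smooth quadratic GC bias on
#'   expected depth (0 disables; 0.2 gives +/-20% across the GC range).
#' @param paper_scale If `TRUE`, use 20,000 bins.
#' @param seed Optional RNG seed.
#' @return A list of class `cnv_sim_config`.
#' @export
cnv_sim_config <- function(n_bins = 2000,
                           bin_width = 1e5,
                           gc = NULL,
                           events = NULL,
                           mean_depth = 150,
                           gc_bias_amplitude = 0,
                           paper_scale = FALSE,
                           seed = NULL) {
  if (paper_scale) n_bins <- 20000
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (is.null(events)) {
    events <- tibble(start_bin = integer(), end_bin = integer(),
                     copy_ratio = numeric())
  } else {
    events <- as_tibble(events)
    stop_if_missing_cols(events, c("start_bin", "end_bin", "copy_ratio"),
                         "events")
    if (any(events$start_bin < 0) || any(events$end_bin > n_bins) ||
        any(events$start_bin >= events$end_bin)) {
      abort("events must satisfy 0 <= start_bin < end_bin <= n_bins")
    }
    if (any(events$copy_ratio <= 0)) abort("copy_ratio must be positive")
  }
  if (!is.null(gc) && (length(gc) != n_bins || any(gc <= 0) || any(gc >= 1))) {
    abort("gc must have one value per bin, strictly inside (0, 1)")
  }
  structure(list(n_bins = n_bins, bin_width = bin_width, gc = gc,
                 events = events, mean_depth = mean_depth,
                 gc_bias_amplitude = gc_bias_amplitude, seed = seed),
            class = "cnv_sim_config")
}

#' Simulate binned read counts for one copy-number sample
#'
#' Counts are Poisson with mean `mean_depth * copy_ratio(bin) * bias(gc)`,
#' where `bias` is a smooth quadratic function of GC fraction normalized to
#' mean 1 across the genome. The true segmentation implied by the implanted
#' events is returned alongside.
#'
#' @param config A [cnv_sim_config()].
#' @return A list of class `cnv_sim` with elements
#'   \describe{
#'     \item{bins}{tibble: chrom, start, end (bp, 0-based half-open), gc,
#'       count, true_ratio}
#'     \item{true_segments}{tibble: chrom, start_bin, end_bin (half-open),
#'       copy_ratio}
#'     \item{config}{the input configuration}
#'   }
#' @export
#' @examples
#' sim <- simulate_cnv_sample(cnv_sim_config(n_bins = 200, seed = 1))
#' head(sim$bins)
simulate_cnv_sample <- function(config) {
  stopifnot(inherits(config, "cnv_sim_config"))
  with_seed(config$seed, {
    n <- config$n_bins
    gc <- config$gc
    if (is.null(gc)) {
      gc <- 0.45 + 0.12 * sin(seq(0, 6 * pi, length.out = n)) +
        rnorm(n, 0, 0.015)
      gc <- clip(gc, 0.30, 0.62)
    }
    ratio <- rep(1, n)
    ev <- config$events
    for (i in seq_len(nrow(ev))) {
      ratio[(ev$start_bin[i] + 1):ev$end_bin[i]] <- ev$copy_ratio[i]
    }
    bias <- if (config$gc_bias_amplitude > 0) {
      gcc <- (gc - mean(gc)) / (max(gc) - min(gc) + 1e-12)
      b <- 1 + config$gc_bias_amplitude * (2 * gcc - 4 * gcc^2)
      pmax(b, 0.05) / mean(pmax(b, 0.05))
    } else rep(1, n)
    mu <- config$mean_depth * ratio * bias
    counts <- rpois(n, mu)

    bins <- tibble(
      chrom = "chrS",
      start = (seq_len(n) - 1) * config$bin_width,
      end = seq_len(n) * config$bin_width,
      gc = gc, count = counts, true_ratio = ratio
    )
    # true segments: runs of constant ratio
    r <- rle(ratio)
    ends <- cumsum(r$lengths)
    true_segments <- tibble(
      chrom = "chrS",
      start_bin = c(0L, ends[-length(ends)]),
      end_bin = as.integer(ends),
      copy_ratio = r$values
    )
    structure(list(bins = bins, true_segments = true_segments,
                   config = config),
              class = "cnv_sim")
  })
}

#' Simulate a drug-combination dose matrix
#'
#' Builds a long-format viability table over a dose grid, including the
#' zero-dose row and column (single agents and vehicle). Combined fractional
#' inhibition follows the Bliss-independence expectation
#' `eA + eB - eA * eB` plus an additive interaction term, clipped to
#' \[0, 1\]; viability is `1 - inhibition` with optional multiplicative
#' lognormal noise, clipped to \[0, 1.2\].
#'
#' @param doses_a,doses_b Positive dose levels (molar) for the two agents.
#' @param effect_a,effect_b Single-agent fractional inhibitions in \[0, 1\],
#'   one per dose level.
#' @param interaction Additive excess inhibition: a scalar or a
#'   `length(doses_a) x length(doses_b)` matrix (rows = agent A).
#' @param noise_cv Lognormal CV of the viability readout.
#' @param n_replicates Replicate measurements per dose pair.
#' @param seed Optional RNG seed.
#' @return Tibble: dose_a, dose_b, replicate, viability, true_excess.
#' @export
simulate_dose_matrix <- function(doses_a, doses_b, effect_a, effect_b,
                                 interaction = 0, noise_cv = 0,
                                 n_replicates = 1, seed = NULL) {
  if (any(effect_a < 0 | effect_a > 1) || any(effect_b < 0 | effect_b > 1)) {
    abort("single-agent inhibitions must lie in [0, 1]")
  }
  stopifnot(length(doses_a) == length(effect_a),
            length(doses_b) == length(effect_b),
            all(doses_a > 0), all(doses_b > 0))
  na <- length(doses_a); nb <- length(doses_b)
  inter <- if (is.matrix(interaction)) interaction else
    matrix(interaction, na, nb)
  stopifnot(nrow(inter) == na, ncol(inter) == nb)

  da <- c(0, doses_a); db <- c(0, doses_b)
  ea <- c(0, effect_a); eb <- c(0, effect_b)
  grid <- tidyr::expand_grid(ia = seq_along(da), ib = seq_along(db),
                             replicate = seq_len(n_replicates))
  with_seed(seed, {
    e_exp <- ea[grid$ia] + eb[grid$ib] - ea[grid$ia] * eb[grid$ib]
    exc <- ifelse(grid$ia > 1 & grid$ib > 1,
                  inter[cbind(pmax(grid$ia - 1, 1), pmax(grid$ib - 1, 1))], 0)
    e_true <- clip(e_exp + exc, 0, 1)
    v <- (1 - e_true) * rlnorm_cv(nrow(grid), noise_cv)
    tibble(
      dose_a = da[grid$ia], dose_b = db[grid$ib],
      replicate = grid$replicate,
      viability = clip(v, 0, 1.2),
      true_excess = clip(e_true, 0, 1) - e_exp
    )
  })
}

#' One-compartment oral PK concentration curve
#'
#' `C(t) = D * ka / (V * (ka - ke)) * (exp(-ke t) - exp(-ka t))`; the
#' `ka == ke` degenerate case uses the limit form
#' `C(t) = D * ka * t / V * exp(-ka t)`.
#'
#' @param t Time (h), non-negative.
#' @param dose Administered dose (amount units; concentration comes out in
#'   amount / volume units of `V`).
#' @param ka,ke Absorption and elimination rate constants (1/h), positive.
#' @param V Volume of distribution.
#' @return Concentration vector.
#' @export
pk_concentration <- function(t, dose, ka, ke, V) {
  stopifnot(ka > 0, ke > 0, V > 0)
  if (isTRUE(all.equal(ka, ke))) {
    dose * ka * t / V * exp(-ka * t)
  } else {
    dose * ka / (V * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Simulate linked pharmacokinetic-pharmacodynamic time courses
#'
#' Concentration follows the one-compartment oral model per dose level and
#' tissue (tissues scale blood exposure by a partition factor); response is
#' the inhibitory sigmoid `1 / (1 + (C / ec50)^hill)` (fraction of vehicle,
#' so response is 1 at C = 0 and 0.5 at C = ec50).
#'
#' @param doses Dose levels (amount units).
#' @param times Sampling times (h), ascending.
#' @param ka,ke Absorption/elimination rate constants (1/h).
#' @param V Volume of distribution.
#' @param ec50_pd Pharmacodynamic EC50 in concentration units.
#' @param hill Hill coefficient (> 0).
#' @param tissues Named numeric vector of tissue partition factors relative
#'   to blood (default `c(blood = 1, tumour = 3)`).
#' @param noise_cv Lognormal CV applied to concentrations and responses.
#' @param seed Optional RNG seed.
#' @return A list of class `pkpd_sim`: `concentration` (tibble: dose, tissue,
#'   time, conc), `response` (tibble: dose, time, conc, response, computed in
#'   the first tissue carrying the PD effect — the last listed tissue, by
#'   convention the tumour), and `config`.
#' @export
simulate_pkpd <- function(doses, times, ka = 1.2, ke = 0.2, V = 1,
                          ec50_pd = 142, hill = 1.5,
                          tissues = c(blood = 1, tumour = 3),
                          noise_cv = 0, seed = NULL) {
  stopifnot(ka > 0, ke > 0, V > 0, ec50_pd > 0, hill > 0,
            !is.unsorted(times))
  with_seed(seed, {
    conc <- tidyr::expand_grid(dose = doses, tissue = names(tissues),
                               time = times) %>%
      mutate(conc = pk_concentration(.data$time, .data$dose, ka, ke, V) *
               unname(tissues[.data$tissue]) *
               rlnorm_cv(dplyr::n(), noise_cv))
    pd_tissue <- names(tissues)[length(tissues)]
    resp <- conc %>%
      filter(.data$tissue == pd_tissue) %>%
      mutate(response = 1 / (1 + (.data$conc / ec50_pd)^hill) *
               rlnorm_cv(dplyr::n(), noise_cv)) %>%
      select("dose", "time", "conc", "response")
    structure(list(concentration = conc, response = resp,
                   config = list(doses = doses, times = times, ka = ka,
                                 ke = ke, V = V, ec50_pd = ec50_pd,
                                 hill = hill, tissues = tissues,
                                 noise_cv = noise_cv, seed = seed)),
              class = "pkpd_sim")
  })
}
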