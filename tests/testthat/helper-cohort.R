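# One synthetic resistance-genomics cohort: focal amplicons (ratio 2, 10
# bins) implanted in 7/11 "resistant" vs 3/36 "control" samples, each sample
# run through the full counts -> GC -> normalize -> CBS -> focal-call chain,
# then the cohort gain frequencies compared by Fisher's exact test.
cohort_fisher_p <- function(seed, n_bins = 150, n_perm = 1000) {
  gain <- tibble::tibble(start_bin = 60L, end_bin = 70L, copy_ratio = 2)
  has_gain <- c(rep(c(TRUE, FALSE), c(7, 4)), rep(c(TRUE, FALSE), c(3, 33)))
  calls <- vapply(seq_along(has_gain), function(i) {
    s <- simulate_cnv_sample(cnv_sim_config(
      n_bins = n_bins, events = if (has_gain[i]) gain else NULL,
      gc_bias_amplitude = 0.2, seed = seed * 1000 + i))
    out <- cnv_pipeline(s$bins, n_perm = n_perm, seed = seed * 1000 + i)
    f <- out$segments[out$segments$event_class == "focal_gain", ]
    any(f$start_bin < 70 & f$end_bin > 60)
  }, logical(1))
  compare_gain_frequency(sum(calls[1:11]), 11,
                         sum(calls[-(1:11)]), 36)$p_value
}
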