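#' GC-bias correction of binned read counts
#'
#' Fits a LOWESS curve of count on GC fraction and divides each bin's count
#' by the fitted value at its GC, rescaled by the genome-wide mean count so
#' the overall scale is preserved:
#' `corrected(i) = count(i) / max(eps, fit(gc(i))) * mean(count)`.
#'
#' @param bins Tibble with columns `chrom, start, end, gc, count`.
#' @param span LOWESS smoother span (default 0.3).
#' @return `bins` with a `corrected` column added.
#' @export
gc_correct <- function(bins, span = 0.3) {
  stop_if_missing_cols(bins, c("chrom", "start", "end", "gc", "count"),
                       "bins")
  if (all(bins$count == 0)) abort("all bin counts are zero")
  if (sum(bins$count > 0) < 50) {
    abort("need at least 50 bins with nonzero counts")
  }
  if (any(bins$gc <= 0 | bins$gc >= 1)) abort("gc must lie strictly in (0, 1)")
  fit <- lowess(bins$gc, bins$count, f = span)
  at <- approx(fit$x, fit$y, xout = bins$gc, rule = 2, ties = mean)$y
  mc <- mean(bins$count)
  eps <- 1e-6 * mc
  bins %>% mutate(corrected = .data$count / pmax(eps, at) * mc)
}

#' Normalize corrected counts to the genome mean
#'
#' Copy number is inferred relative to the mean of the genome rather than as
#' absolute states: `ratio(i) = corrected(i) / mean(corrected)`, so the mean
#' ratio is exactly 1.
#'
#' @param bins Tibble with a `corrected` column (see [gc_correct()]); falls
#'   back to `count` when `corrected` is absent.
#' @return `bins` with a `ratio` column added.
#' @export
normalize_to_genome_mean <- function(bins) {
  src <- if ("corrected" %in% names(bins)) bins$corrected else bins$count
  m <- mean(src)
  if (!is.finite(m) || m <= 0) abort("mean corrected count must be positive")
  bins %>% mutate(ratio = src / m)
}

#' Circular binary segmentation of per-bin copy-number ratios
#'
#' Recursive changepoint detection: within each interval the pair of
#' circular breakpoints maximizing the two-sample t statistic between the
#' arc and its complement is located by exhaustive scan; the split is
#' accepted when the permutation p-value (label permutations of the bin
#' values within the interval) is at most `alpha`, and the procedure recurses
#' on the resulting pieces. Adjacent segments whose means differ by less
#' than `min_seg_delta` are merged afterwards. Deterministic given `seed`.
#'
#' @param bins Tibble with columns `chrom, start, end, ratio` (bins sorted,
#'   non-overlapping within chromosome).
#' @param alpha Permutation significance level in (0, 1), default 0.01.
#' @param n_perm Number of permutations (default 1000).
#' @param min_seg_delta Merge threshold on adjacent segment means
#'   (default 0.1, linear-ratio units).
#' @param use_log Segment `log2(ratio)` instead of linear ratios (means are
#'   still reported on the linear scale).
#' @param seed Optional RNG seed.
#' @return Tibble of segments: `chrom, start_bin, end_bin` (0-based
#'   half-open bin indices within chromosome), `loc_start, loc_end` (bp),
#'   `n_bins, mean_ratio`.
#' @export
segment_cbs <- function(bins, alpha = 0.01, n_perm = 1000,
                        min_seg_delta = 0.1, use_log = FALSE, seed = NULL) {
  stop_if_missing_cols(bins, c("chrom", "start", "end", "ratio"), "bins")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  with_seed(seed, {
    bins %>%
      group_by(.data$chrom) %>%
      dplyr::group_modify(function(df, key) {
        df <- arrange(df, .data$start)
        x <- if (use_log) log2(pmax(df$ratio, 1e-6)) else df$ratio
        cuts <- cbs_find_cuts(x, alpha, n_perm)
        seg_bounds <- c(0L, cuts, length(x))
        segs <- tibble(
          start_bin = seg_bounds[-length(seg_bounds)],
          end_bin = seg_bounds[-1]
        )
        segs <- merge_segments(segs, df$ratio, min_seg_delta)
        segs %>%
          mutate(loc_start = df$start[.data$start_bin + 1],
                 loc_end = df$end[.data$end_bin],
                 n_bins = .data$end_bin - .data$start_bin,
                 mean_ratio = purrr::map2_dbl(
                   .data$start_bin, .data$end_bin,
                   function(s, e) mean(df$ratio[(s + 1):e])))
      }) %>%
      ungroup()
  })
}

# recursive cut finder on a numeric vector; returns sorted internal cut
# positions (0-based: a cut at k separates bins [1..k] from [k+1..])
cbs_find_cuts <- function(x, alpha, n_perm) {
  m <- length(x)
  if (m < 3) return(integer())
  sp <- cbs_max_split(x)
  if (sp$t <= 0) return(integer())
  p <- cbs_perm_p(x, sp$t, n_perm, alpha)
  if (p > alpha) return(integer())
  local_cuts <- sort(unique(c(sp$i, sp$j)))
  local_cuts <- local_cuts[local_cuts > 0 & local_cuts < m]
  if (length(local_cuts) == 0) return(integer())
  pieces <- c(0L, local_cuts, m)
  out <- local_cuts
  for (k in seq_len(length(pieces) - 1)) {
    lo <- pieces[k] + 1L; hi <- pieces[k + 1]
    sub <- cbs_find_cuts(x[lo:hi], alpha, n_perm)
    out <- c(out, sub + pieces[k])
  }
  sort(unique(out))
}

# merge adjacent segments whose means differ by < delta (closest pair first)
merge_segments <- function(segs, ratio, delta) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    means <- vapply(seq_len(nrow(segs)), function(i) {
      mean(ratio[(segs$start_bin[i] + 1):segs$end_bin[i]])
    }, numeric(1))
    diffs <- abs(diff(means))
    if (all(diffs >= delta)) return(segs)
    i <- which.min(diffs)
    segs$end_bin[i] <- segs$end_bin[i + 1]
    segs <- segs[-(i + 1), ]
  }
}

#' Call focal copy-number gains from segments
#'
#' A segment is a focal gain when its mean normalized ratio exceeds
#' `ratio_threshold` and its physical length is at most `focality_limit`;
#' gains longer than the limit are classed as broad gains; everything else
#' is `none`.
#'
#' @param segments Segment tibble (see [segment_cbs()]).
#' @param ratio_threshold Gain threshold on the segment mean ratio
#'   (default 1.5; the call requires strictly greater).
#' @param focality_limit Maximum physical length in bp of a focal event
#'   (default 2e7, i.e. 20 Mb).
#' @return `segments` with an `event_class` column
#'   (`focal_gain` / `broad_gain` / `none`).
#' @export
call_focal_gains <- function(segments, ratio_threshold = 1.5,
                             focality_limit = 2e7) {
  stop_if_missing_cols(segments, c("chrom", "loc_start", "loc_end",
                                   "mean_ratio"), "segments")
  segments %>%
    mutate(event_class = case_when(
      .data$mean_ratio > ratio_threshold &
        (.data$loc_end - .data$loc_start) <= focality_limit ~ "focal_gain",
      .data$mean_ratio > ratio_threshold ~ "broad_gain",
      TRUE ~ "none"
    ))
}

#' Annotate copy-number events with overlapping genes
#'
#' Half-open interval overlap (an event `[100, 200)` does not overlap a gene
#' `[200, 300)`); a gene is listed when it overlaps the event by at least
#' 1 bp.
#'
#' @param events Tibble with columns `chrom, loc_start, loc_end`.
#' @param genes Tibble with columns `chrom, start, end, gene` (0-based
#'   half-open, BED-style).
#' @return `events` with a `genes` column (comma-separated gene names, `""`
#'   when none overlap).
#' @export
annotate_genes <- function(events, genes) {
  stop_if_missing_cols(events, c("chrom", "loc_start", "loc_end"), "events")
  stop_if_missing_cols(genes, c("chrom", "start", "end", "gene"), "genes")
  if (any(genes$end <= genes$start)) abort("malformed gene intervals")
  events$genes <- vapply(seq_len(nrow(events)), function(i) {
    g <- genes[genes$chrom == events$chrom[i], ]
    if (nrow(g) == 0) return("")
    ev <- IRanges::IRanges(start = events$loc_start[i] + 1,
                           end = events$loc_end[i])
    gr <- IRanges::IRanges(start = g$start + 1, end = g$end)
    hit <- IRanges::findOverlaps(ev, gr, minoverlap = 1)
    paste(g$gene[S4Vectors::subjectHits(hit)], collapse = ",")
  }, character(1))
  events
}

#' Two-sided Fisher's exact comparison of gain frequencies
#'
#' Compares event counts between two cohorts (e.g. focal gains at a locus in
#' resistant versus control tumours) with the exact hypergeometric test:
#' the two-sided p-value sums the probabilities of all 2x2 tables with the
#' same margins whose point probability does not exceed that of the observed
#' table.
#'
#' @param k1,n1 Events and cohort size in cohort 1.
#' @param k2,n2 Events and cohort size in cohort 2.
#' @return One-row tibble: `k1, n1, k2, n2, odds_ratio, p_value`.
#' @export
#' @examples
#' compare_gain_frequency(7, 11, 3, 36) # printed as P = 0.0003
compare_gain_frequency <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2) {
    abort("need 0 <= k <= n for both cohorts")
  }
  K <- k1 + k2
  support <- max(0, K - n2):min(K, n1)
  dens <- dhyper(support, n1, n2, K)
  d_obs <- dhyper(k1, n1, n2, K)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  or <- (k1 * (n2 - k2)) / (k2 * (n1 - k1))
  tibble(k1 = k1, n1 = n1, k2 = k2, n2 = n2,
         odds_ratio = or, p_value = min(1, p))
}

#' Run the copy-number pipeline on one sample
#'
#' Convenience chain: [gc_correct()] -> [normalize_to_genome_mean()] ->
#' [segment_cbs()] -> [call_focal_gains()].
#'
#' @param bins Bin-count tibble (`chrom, start, end, gc, count`).
#' @param span LOWESS span for GC correction.
#' @inheritParams segment_cbs
#' @inheritParams call_focal_gains
#' @return List with `bins` (ratios added) and `segments` (with event
#'   classes).
#' @export
cnv_pipeline <- function(bins, span = 0.3, alpha = 0.01, n_perm = 1000,
                         min_seg_delta = 0.1, ratio_threshold = 1.5,
                         focality_limit = 2e7, seed = NULL) {
  b <- bins %>% gc_correct(span = span) %>% normalize_to_genome_mean()
  segs <- segment_cbs(b, alpha = alpha, n_perm = n_perm,
                      min_seg_delta = min_seg_delta, seed = seed) %>%
    call_focal_gains(ratio_threshold = ratio_threshold,
                     focality_limit = focality_limit)
  list(bins = b, segments = segs)
}

#' Write segments as a SEG file
#'
#' SEG output is 1-based inclusive per the format convention (internal
#' coordinates are 0-based half-open).
#'
#' @param segments Segment tibble (see [segment_cbs()]).
#' @param sample Sample identifier for the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, sample, path) {
  out <- data.frame(
    ID = sample,
    chrom = segments$chrom,
    loc.start = segments$loc_start + 1,
    loc.end = segments$loc_end,
    num.mark = segments$n_bins,
    seg.mean = segments$mean_ratio
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
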