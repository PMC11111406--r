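#' Plot a fitted dose-response curve
#'
#' @param object A `fourpl_fit`.
#' @param data Optional tibble of observed points (`dose_molar, viability`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fourpl_fit <- function(object, data = NULL, ...) {
  rng <- log10(object$dose_range)
  grid <- tibble(dose_molar = 10^seq(rng[1], rng[2], length.out = 200))
  grid$viability <- predict(object, grid$dose_molar)
  p <- ggplot2::ggplot(grid,
                       ggplot2::aes(x = .data$dose_molar,
                                    y = .data$viability)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (M)", y = "viability (fraction)") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(data = data, alpha = 0.7)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a copy-number profile with its segments
#'
#' Per-bin ratios with segment means overlaid and the focal-gain threshold
#' marked.
#'
#' @param bins Tibble with `chrom, start, ratio`.
#' @param segments Optional segment tibble (see [segment_cbs()]).
#' @param ratio_threshold Gain threshold line (default 1.5).
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(bins, segments = NULL, ratio_threshold = 1.5) {
  p <- ggplot2::ggplot(bins, ggplot2::aes(x = .data$start / 1e6,
                                          y = .data$ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = ratio_threshold, linetype = "dashed",
                        color = "darkgreen") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "normalized depth ratio") +
    ggplot2::theme_minimal()
  if (!is.null(segments)) {
    p <- p + ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = .data$loc_start / 1e6, xend = .data$loc_end / 1e6,
                   y = .data$mean_ratio, yend = .data$mean_ratio),
      color = "red", linewidth = 1)
  }
  p
}

#' Heatmap of Bliss excess over a dose matrix
#'
#' @param excess_df Output of [bliss_excess()].
#' @return A ggplot object.
#' @export
plot_synergy_matrix <- function(excess_df) {
  df <- excess_df %>%
    group_by(.data$dose_a, .data$dose_b) %>%
    summarise(excess = mean(.data$excess), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$dose_a),
                                   y = factor(.data$dose_b),
                                   fill = .data$excess)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0) +
    ggplot2::labs(x = "drug A dose", y = "drug B dose",
                  fill = "Bliss excess") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of best tumour responses
#'
#' @param responses Output of [tumour_response()].
#' @return A ggplot object.
#' @export
plot_waterfall <- function(responses) {
  df <- responses %>% arrange(dplyr::desc(.data$best_response)) %>%
    mutate(rank = row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$best_response)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "tumour", y = "best response (% change)") +
    ggplot2::theme_minimal()
}
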