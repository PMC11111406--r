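#' Log-viability relative to the plate negative controls
#'
#' For each cell line on each plate, log-viability is the corrected
#' log2(MFI) minus the median corrected log2(MFI) of the same line in the
#' plate's negative-control wells: `LV = log2(x) - log2(mu_minus)`. Vehicle
#' wells therefore sit at 0 by construction, and a halving of signal gives
#' -1.
#'
#' @param calibrated Calibrated cell-barcode tibble (see
#'   [calibrate_plates()]).
#' @return Tibble of treatment-well rows with columns `cell_line, plate_id,
#'   batch, pool, replicate, dose_molar, log_viability`.
#' @export
compute_log_viability <- function(calibrated) {
  stop_if_missing_cols(calibrated,
                       c("plate_id", "treatment", "barcode_id",
                         "corrected_log2_mfi"), "calibrated")
  mu_minus <- calibrated %>%
    filter(.data$treatment == "negative_control") %>%
    group_by(.data$plate_id, .data$barcode_id) %>%
    summarise(mu_minus = median(.data$corrected_log2_mfi), .groups = "drop")
  if (nrow(mu_minus) == 0) abort("no negative-control wells found")
  calibrated %>%
    filter(.data$treatment == "treatment") %>%
    inner_join(mu_minus, by = c("plate_id", "barcode_id")) %>%
    mutate(log_viability = .data$corrected_log2_mfi - .data$mu_minus) %>%
    select(cell_line = "barcode_id", "plate_id", dplyr::any_of(c("batch", "pool", "replicate")),
           "dose_molar", "log_viability")
}

#' Empirical-Bayes batch correction of a viability matrix
#'
#' Location-scale batch adjustment (ComBat): per-feature standardization,
#' per-batch additive and multiplicative effect estimates shrunk toward
#' across-batch priors, then back-transformation. A single-batch matrix is
#' returned unchanged. Features with (near-)zero variance are passed through
#' uncorrected. When any batch has a single sample, the adjustment falls
#' back to location-only (mean) correction for the whole matrix.
#'
#' @param mat Numeric matrix, features (conditions) x samples.
#' @param batch Batch label per column.
#' @return Corrected matrix with the same dimensions and dimnames.
#' @export
correct_batch_effects <- function(mat, batch) {
  stopifnot(is.matrix(mat), length(batch) == ncol(mat))
  batch <- as.factor(batch)
  if (nlevels(droplevels(batch)) < 2) return(mat)
  sizes <- table(droplevels(batch))
  mean_only <- any(sizes < 2)
  if (mean_only) {
    inform("batch with a single sample: falling back to location-only adjustment")
  }
  sds <- apply(mat, 1, sd)
  fixed <- !is.finite(sds) | sds < 1e-10
  out <- mat
  if (sum(!fixed) >= 1) {
    sub <- mat[!fixed, , drop = FALSE]
    corrected <- suppressMessages(
      sva::ComBat(dat = sub, batch = batch, mean.only = mean_only)
    )
    out[!fixed, ] <- corrected
  }
  out
}

#' Collapse replicate log-viability to a treatment-level profile
#'
#' Median log-viability across replicates for each cell line x dose.
#'
#' @param viability Long tibble with columns `cell_line, dose_molar,
#'   log_viability` (and anything else, ignored).
#' @return Tibble: `cell_line, dose_molar, log_viability, viability`, where
#'   `viability = 2^log_viability` clipped to \[0, 1.2\] for curve fitting.
#' @export
collapse_replicates <- function(viability) {
  stop_if_missing_cols(viability, c("cell_line", "dose_molar",
                                    "log_viability"), "viability")
  viability %>%
    group_by(.data$cell_line, .data$dose_molar) %>%
    summarise(log_viability = median(.data$log_viability),
              .groups = "drop") %>%
    mutate(viability = clip(2^.data$log_viability, 0, 1.2))
}

#' Process a pooled-barcode screen from plates to treatment-level profiles
#'
#' Runs the full screen-processing chain: spike-in calibration of every well,
#' control-separability QC per cell line x replicate, exclusion of lines
#' with error rate above `error_max`, dynamic range below `dr_min`, or fewer
#' than `min_passing_replicates` passing replicates, log-viability relative
#' to plate negative controls, optional empirical-Bayes batch correction
#' across pool/culture batches, and median collapse of replicates.
#'
#' @param plates Plate tibble (schema of [simulate_screen()]'s `plates`).
#' @param error_max,dr_min,min_passing_replicates QC thresholds, see
#'   [apply_qc_filters()].
#' @param correct_batch Apply [correct_batch_effects()] when more than one
#'   batch is present (default `TRUE`).
#' @return A list of class `screen_result`:
#'   \describe{
#'     \item{qc}{per line x replicate QC tibble with inclusion flags}
#'     \item{viability}{long log-viability tibble before batch correction}
#'     \item{corrected}{long log-viability tibble after batch correction}
#'     \item{profile}{collapsed treatment-level tibble
#'       (`cell_line, dose_molar, log_viability, viability`)}
#'   }
#' @export
process_screen <- function(plates, error_max = 0.05, dr_min = 1.74,
                           min_passing_replicates = 2,
                           correct_batch = TRUE) {
  calibrated <- calibrate_plates(plates)
  qc <- screen_qc_metrics(calibrated) %>%
    apply_qc_filters(error_max = error_max, dr_min = dr_min,
                     min_passing_replicates = min_passing_replicates)

  keep <- qc %>% filter(.data$included, .data$passes) %>%
    select("cell_line", "replicate")
  lv <- compute_log_viability(calibrated) %>%
    inner_join(keep, by = c("cell_line", "replicate"))

  corrected <- lv
  if (correct_batch && "batch" %in% names(lv) &&
      dplyr::n_distinct(lv$batch) > 1) {
    wide <- lv %>%
      mutate(sample = paste(.data$cell_line, .data$replicate, sep = "|")) %>%
      select("sample", "dose_molar", "log_viability") %>%
      tidyr::pivot_wider(names_from = "sample",
                         values_from = "log_viability") %>%
      arrange(.data$dose_molar)
    mat <- as.matrix(wide[, -1, drop = FALSE])
    # columns = samples (line x replicate); rows = dose features
    batch_of <- lv %>%
      mutate(sample = paste(.data$cell_line, .data$replicate, sep = "|")) %>%
      distinct(.data$sample, .data$batch)
    bvec <- batch_of$batch[match(colnames(mat), batch_of$sample)]
    rownames(mat) <- as.character(wide$dose_molar)
    cmat <- correct_batch_effects(mat, bvec)
    long <- as_tibble(cmat) %>%
      mutate(dose_molar = wide$dose_molar) %>%
      tidyr::pivot_longer(-"dose_molar", names_to = "sample",
                          values_to = "log_viability") %>%
      tidyr::separate_wider_delim("sample", delim = "|",
                                  names = c("cell_line", "replicate")) %>%
      mutate(replicate = as.integer(.data$replicate))
    corrected <- lv %>%
      select(-"log_viability") %>%
      inner_join(long, by = c("cell_line", "replicate", "dose_molar"))
  }

  profile <- collapse_replicates(corrected)
  structure(list(qc = qc, viability = lv, corrected = corrected,
                 profile = profile),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  inc <- x$qc %>% distinct(.data$cell_line, .data$included)
  cat("<screen_result>\n")
  cat(sprintf("  cell lines: %d included / %d total\n",
              sum(inc$included), nrow(inc)))
  cat(sprintf("  profile: %d lines x %d doses\n",
              dplyr::n_distinct(x$profile$cell_line),
              dplyr::n_distinct(x$profile$dose_molar)))
  invisible(x)
}
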