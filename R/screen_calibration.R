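#' Spike-in reference profile for a plate
#'
#' For each of the ten spike-in control barcodes, takes the median of its
#' log2(MFI) values across the plate's negative-control wells. The result is
#' the per-plate reference that per-well calibration maps onto.
#'
#' @param plate Tibble of plate rows (one per well x barcode) with columns
#'   `well, treatment, barcode_id, barcode_class, log2_mfi`.
#' @return Tibble: `barcode_id, ref_log2_mfi`, in spike-in barcode order.
#' @export
build_reference_profile <- function(plate) {
  stop_if_missing_cols(plate, c("well", "treatment", "barcode_id",
                                "barcode_class", "log2_mfi"), "plate")
  neg <- plate %>%
    filter(.data$treatment == "negative_control",
           .data$barcode_class == "spike")
  if (nrow(neg) == 0) abort("plate has no negative-control wells")
  spikes <- sort(unique(plate$barcode_id[plate$barcode_class == "spike"]))
  # every control well must carry the full spike-in set
  per_well <- neg %>% group_by(.data$well) %>%
    summarise(n_spike = dplyr::n_distinct(.data$barcode_id))
  bad <- per_well$well[per_well$n_spike < length(spikes)]
  if (length(bad) > 0) {
    abort(sprintf("negative-control well(s) missing spike-in barcodes: %s",
                  paste(bad, collapse = ", ")))
  }
  neg %>%
    group_by(barcode_id = factor(.data$barcode_id, levels = spikes)) %>%
    summarise(ref_log2_mfi = median(.data$log2_mfi)) %>%
    mutate(barcode_id = as.character(.data$barcode_id)) %>%
    arrange(.data$barcode_id)
}

# Monotone smooth map through (x, y) calibration pairs with linear
# extrapolation beyond the data range. Ties in x are collapsed by averaging
# y; y is passed through isotonic regression so the shape-preserving Hermite
# interpolant (monoH.FC) is guaranteed non-decreasing.
monotone_map <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  ux <- unique(x)
  if (length(ux) < length(x)) {
    y <- vapply(ux, function(v) mean(y[x == v]), numeric(1))
    x <- ux
  }
  if (length(x) < 4) {
    abort("insufficient calibration points: need at least 4 usable spike-in pairs")
  }
  y <- isoreg(x, y)$yf
  f <- splinefun(x, y, method = "monoH.FC")
  lo <- x[1]; hi <- x[length(x)]
  dlo <- f(lo, deriv = 1); dhi <- f(hi, deriv = 1)
  function(z) {
    out <- f(z)
    below <- z < lo; above <- z > hi
    out[below] <- f(lo) + dlo * (z[below] - lo)
    out[above] <- f(hi) + dhi * (z[above] - hi)
    out
  }
}

#' Calibrate one well's cell-barcode signals against the plate reference
#'
#' Fits a monotone smooth map from the well's ten spike-in log2(MFI) levels
#' to the plate reference profile, then applies it to the well's cell-barcode
#' log2(MFI) values. This removes per-well amplification/detection artifacts
#' so wells are comparable. The map is a shape-preserving monotone cubic
#' interpolant through the ten pairs (non-decreasing over the data range,
#' linear extrapolation beyond it).
#'
#' @param well_spikes Numeric vector: the well's spike-in log2(MFI) values,
#'   in the same barcode order as `reference`.
#' @param reference Numeric vector: the plate reference log2(MFI) levels
#'   (see [build_reference_profile()]).
#' @param values Numeric vector of cell-barcode log2(MFI) values to correct.
#' @return Corrected log2(MFI) values, same length as `values`.
#' @export
#' @examples
#' ref <- 1:10
#' calibrate_well(ref + 1.5, ref, c(3.2, 7.5)) # uniform shift removed
calibrate_well <- function(well_spikes, reference, values) {
  stopifnot(length(well_spikes) == length(reference))
  ok <- is.finite(well_spikes) & is.finite(reference)
  g <- monotone_map(well_spikes[ok], reference[ok])
  g(values)
}

#' Calibrate every well of a plate table
#'
#' Applies [build_reference_profile()] and [calibrate_well()] plate by plate,
#' returning the cell-barcode rows with a `corrected_log2_mfi` column.
#'
#' @param plates Plate tibble (see [simulate_screen()] output schema).
#' @return Tibble of cell-barcode rows with `corrected_log2_mfi` added.
#' @export
calibrate_plates <- function(plates) {
  stop_if_missing_cols(plates, c("plate_id", "well", "treatment",
                                 "barcode_id", "barcode_class", "log2_mfi"),
                       "plates")
  plates %>%
    group_by(.data$plate_id) %>%
    dplyr::group_modify(function(plate, key) {
      ref <- build_reference_profile(plate)
      plate %>%
        group_by(.data$well) %>%
        dplyr::group_modify(function(wdf, wkey) {
          sp <- wdf %>% filter(.data$barcode_class == "spike") %>%
            arrange(.data$barcode_id)
          cells <- wdf %>% filter(.data$barcode_class == "cell")
          if (nrow(sp) < nrow(ref)) {
            abort(sprintf("well %s is missing spike-in barcodes", wkey$well))
          }
          cells$corrected_log2_mfi <-
            calibrate_well(sp$log2_mfi[match(ref$barcode_id, sp$barcode_id)],
                           ref$ref_log2_mfi, cells$log2_mfi)
          cells
        }) %>%
        ungroup()
    }) %>%
    ungroup()
}
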