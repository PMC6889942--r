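# The quantitative markers: pixel/voxel-wise NADH/FAD maps, Surface RR,
# normalized wound area, Volumetric RR, and their histograms.

#' Pixel- or voxel-wise NADH/FAD redox map
#'
#' Divides the calibrated NADH image by the calibrated FAD image wherever
#' the wound mask is true and the FAD intensity is at or above a small
#' positive floor. The floor (default 1% of the median calibrated FAD inside
#' the mask) keeps near-zero FAD pixels from contributing unbounded ratios;
#' the excluded fraction is reported.
#'
#' @param nadh,fad Calibrated, masked [channel_frame()]s (2D) or plain
#'   arrays for the volumetric case.
#' @param mask A [wound_mask()] of matching shape.
#' @param fad_floor Positive floor on calibrated FAD, or `NULL` for the
#'   default 1% of the masked median.
#' @return Object of class `redox_map`: `values` (ratios, `NA` where
#'   undefined), `valid_mask`, `n_mask`, `n_valid`, `excluded_fraction`.
#' @export
redox_map <- function(nadh, fad, mask, fad_floor = NULL) {
  get_px <- function(x, ch) {
    if (inherits(x, "channel_frame")) {
      if (!x$calibrated) {
        rw_stop("rw_contract_error", "%s frame must be calibrated before the ratio", ch)
      }
      x$pixels
    } else if (inherits(x, "cryo_stack")) {
      if (!x$flat_corrected) {
        rw_stop("rw_contract_error", "%s stack must be flat-field corrected", ch)
      }
      x$voxels
    } else x
  }
  n <- get_px(nadh, "NADH")
  f <- get_px(fad, "FAD")
  stopifnot(inherits(mask, "wound_mask"))
  if (!identical(dim(n), dim(f)) || !identical(dim(n), dim(mask$mask))) {
    rw_stop("rw_mask_error", "NADH, FAD and mask shapes must agree")
  }
  if (is.null(fad_floor)) {
    med <- stats::median(f[mask$mask])
    fad_floor <- 0.01 * med
  }
  if (!is.finite(fad_floor) || fad_floor <= 0) {
    rw_stop("rw_metric_error", "fad_floor must be a positive number")
  }
  valid <- mask$mask & (f >= fad_floor)
  if (!any(valid)) {
    rw_stop("rw_metric_error", "no valid pixels: all FAD below the floor")
  }
  values <- array(NA_real_, dim = dim(n))
  values[valid] <- n[valid] / f[valid]
  structure(list(values = values, valid_mask = valid,
                 n_mask = sum(mask$mask), n_valid = sum(valid),
                 excluded_fraction = 1 - sum(valid) / sum(mask$mask),
                 fad_floor = fad_floor),
            class = "redox_map")
}

#' @export
print.redox_map <- function(x, ...) {
  cat(sprintf("<redox_map %s, %d/%d valid px, %.2f%% floor-excluded>\n",
              paste(dim(x$values), collapse = "x"), x$n_valid, x$n_mask,
              100 * x$excluded_fraction))
  invisible(x)
}

#' Surface redox ratio of a wound image
#'
#' The mean of the redox-ratio histogram over wound pixels,
#' `SurfaceRR = (1/N) * sum(wound pixel ratios)`. Where the FAD floor
#' excludes pixels the divisor is the number of defined ratios (`n_valid`);
#' both counts are reported so either convention can be reproduced.
#'
#' @param map A 2D [redox_map()].
#' @param subject,group,day Optional metadata carried into the result.
#' @return Object of class `surface_metrics`: `surface_rr`, `n_pixels` (mask
#'   count N), `n_valid`, plus metadata.
#' @export
surface_rr <- function(map, subject = NA_character_, group = NA_character_,
                       day = NA_real_) {
  stopifnot(inherits(map, "redox_map"))
  if (map$n_valid < 1) rw_stop("rw_metric_error", "no valid pixels")
  structure(list(surface_rr = mean(map$values[map$valid_mask]),
                 n_pixels = map$n_mask, n_valid = map$n_valid,
                 subject = subject, group = group, day = day),
            class = "surface_metrics")
}

#' Volumetric redox ratio of a biopsy
#'
#' The volume mean of the voxelwise redox ratio over wound voxels,
#' `VolumetricRR = (1/N_v) * sum(wound voxel ratios)`.
#'
#' @param map A 3D [redox_map()].
#' @inheritParams surface_rr
#' @return Object of class `volumetric_metrics`: `volumetric_rr`,
#'   `n_voxels`, `n_valid`, plus metadata.
#' @export
volumetric_rr <- function(map, subject = NA_character_, group = NA_character_,
                          day = NA_real_) {
  stopifnot(inherits(map, "redox_map"))
  if (map$n_valid < 1) rw_stop("rw_metric_error", "no valid voxels")
  structure(list(volumetric_rr = mean(map$values[map$valid_mask]),
                 n_voxels = map$n_mask, n_valid = map$n_valid,
                 subject = subject, group = group, day = day),
            class = "volumetric_metrics")
}

#' Normalized wound area
#'
#' Wound pixel count at day t over the day-0 count, `N(t)/N(0)`. The pixel
#' size is constant across days, so the physical-area ratio reduces to the
#' pixel-count ratio: 1 at wounding, 0 at complete closure.
#'
#' @param n_t Wound pixel count at day t (>= 0).
#' @param n_0 Wound pixel count at day 0 (> 0).
#' @return Dimensionless area ratio.
#' @export
normalized_area <- function(n_t, n_0) {
  if (length(n_0) != 1 || n_0 <= 0) {
    rw_stop("rw_metric_error", "day-0 pixel count must be > 0")
  }
  if (any(n_t < 0)) rw_stop("rw_metric_error", "pixel counts must be >= 0")
  n_t / n_0
}

#' Redox-ratio histogram
#'
#' Bins the defined ratio values of a redox map; values outside the range
#' accumulate in explicit underflow/overflow bins so the count fractions sum
#' to one over all bins.
#'
#' @param map A [redox_map()].
#' @param n_bins Number of interior bins (>= 1).
#' @param range Length-2 numeric `[lo, hi)`, `lo < hi`.
#' @return List: `breaks` (bin edges), `counts` (interior), `underflow`,
#'   `overflow`, `fraction` (length `n_bins + 2`, ordered underflow,
#'   interior, overflow; sums to 1), `mids` (bin centres).
#' @export
rr_histogram <- function(map, n_bins = 100, range = c(0, 4)) {
  stopifnot(inherits(map, "redox_map"))
  if (n_bins < 1) rw_stop("rw_metric_error", "n_bins must be >= 1")
  if (range[1] >= range[2]) rw_stop("rw_metric_error", "range must satisfy lo < hi")
  v <- map$values[map$valid_mask]
  if (!length(v)) rw_stop("rw_metric_error", "empty redox map")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  idx <- findInterval(v, breaks, rightmost.closed = FALSE)
  underflow <- sum(idx == 0)
  overflow <- sum(idx == n_bins + 1)
  counts <- tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  total <- length(v)
  list(breaks = breaks, counts = counts,
       underflow = underflow, overflow = overflow,
       fraction = c(underflow, counts, overflow) / total,
       mids = (breaks[-1] + breaks[-length(breaks)]) / 2)
}
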