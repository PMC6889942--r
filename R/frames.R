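# Image containers and 16-bit TIFF I/O.

CHANNELS <- c("WHITE", "NADH", "FAD")

#' A single-channel 2D acquisition
#'
#' Raw frames hold camera counts (DN) in `[0, 16383]` (14-bit); calibrated
#' frames are dimensionless (intensity relative to the same-day cuvette
#' reference) and flagged so that double calibration is detected.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param channel One of `"WHITE"`, `"NADH"`, `"FAD"`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param subject,group,day Optional acquisition metadata.
#' @param calibrated Logical; `TRUE` once divided by a cuvette reference.
#' @return An object of class `channel_frame`.
#' @export
channel_frame <- function(pixels, channel, pixel_size_um,
                          subject = NA_character_, group = NA_character_,
                          day = NA_real_, calibrated = FALSE) {
  channel <- match.arg(channel, CHANNELS)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    rw_stop("rw_format_error", "pixels must be a numeric matrix")
  }
  if (any(pixels < 0)) rw_stop("rw_format_error", "negative intensities")
  if (!calibrated && max(pixels) > MAX_DN) {
    rw_stop("rw_format_error",
            "raw %s frame exceeds the 14-bit range (max %g > %d)",
            channel, max(pixels), MAX_DN)
  }
  if (pixel_size_um <= 0) rw_stop("rw_format_error", "pixel_size_um must be > 0")
  structure(list(pixels = pixels, channel = channel,
                 pixel_size_um = pixel_size_um, subject = subject,
                 group = group, day = day, calibrated = isTRUE(calibrated)),
            class = "channel_frame")
}

#' @export
print.channel_frame <- function(x, ...) {
  cat(sprintf("<channel_frame %s %dx%d px @ %g um, %s%s>\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              if (x$calibrated) "calibrated" else "raw DN",
              if (is.na(x$subject)) "" else
                sprintf(", %s day %g", x$subject, x$day)))
  invisible(x)
}

#' A per-channel 3D cryo-imaging volume
#'
#' Holds the voxel intensities of one fluorescence channel of a flash-frozen
#' biopsy together with the flat-field reference frame acquired in the same
#' channel.
#'
#' @param voxels Numeric 3D array of non-negative intensities.
#' @param channel `"NADH"` or `"FAD"`.
#' @param voxel_size_um Length-3 voxel size, micrometres.
#' @param flat_field Positive matrix: the flat-field reference (DN).
#' @param subject,group,day Optional metadata.
#' @param flat_corrected,background_zeroed Processing-state flags.
#' @return An object of class `cryo_stack`.
#' @export
cryo_stack <- function(voxels, channel, voxel_size_um, flat_field = NULL,
                       subject = NA_character_, group = NA_character_,
                       day = NA_real_, flat_corrected = FALSE,
                       background_zeroed = FALSE) {
  channel <- match.arg(channel, c("NADH", "FAD"))
  if (!(is.array(voxels) && length(dim(voxels)) == 3L)) {
    rw_stop("rw_format_error", "voxels must be a 3D array")
  }
  if (any(voxels < 0)) rw_stop("rw_format_error", "negative intensities")
  if (any(voxel_size_um <= 0) || length(voxel_size_um) != 3L) {
    rw_stop("rw_format_error", "voxel_size_um must be 3 positive lengths")
  }
  if (!is.null(flat_field) && any(flat_field <= 0)) {
    rw_stop("rw_calibration_error", "flat field must be strictly positive")
  }
  structure(list(voxels = voxels, channel = channel,
                 voxel_size_um = voxel_size_um, flat_field = flat_field,
                 subject = subject, group = group, day = day,
                 flat_corrected = isTRUE(flat_corrected),
                 background_zeroed = isTRUE(background_zeroed)),
            class = "cryo_stack")
}

#' @export
print.cryo_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<cryo_stack %s %dx%dx%d vox, %s%s>\n", x$channel,
              d[1], d[2], d[3],
              if (x$flat_corrected) "flat-corrected" else "raw DN",
              if (x$background_zeroed) ", background zeroed" else ""))
  invisible(x)
}

#' Binary wound region
#'
#' @param mask Logical matrix (2D) or array (3D) marking wound pixels/voxels.
#' @param source `"auto"` (segmentation) or `"manual"` (loaded mask file).
#' @return An object of class `wound_mask`. Pixel counts are recomputed on
#'   access via [n_pixels()], never cached.
#' @export
wound_mask <- function(mask, source = c("auto", "manual")) {
  source <- match.arg(source)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  structure(list(mask = mask, source = source), class = "wound_mask")
}

#' Number of wound pixels (or voxels) in a mask
#' @param mask A [wound_mask()].
#' @return Integer count of `TRUE` entries.
#' @export
n_pixels <- function(mask) {
  stopifnot(inherits(mask, "wound_mask"))
  sum(mask$mask)
}

#' @export
print.wound_mask <- function(x, ...) {
  cat(sprintf("<wound_mask %s, %d px, %s>\n",
              paste(dim(x$mask), collapse = "x"), n_pixels(x), x$source))
  invisible(x)
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical non-empty masks.
#'
#' @param a,b Logical arrays of equal shape, or [wound_mask()] objects.
#' @return Scalar in `[0, 1]` (`NaN` if both masks are empty).
#' @export
dice <- function(a, b) {
  if (inherits(a, "wound_mask")) a <- a$mask
  if (inherits(b, "wound_mask")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# --- TIFF I/O ---------------------------------------------------------------
# Integer DN frames are stored as 16-bit grayscale TIFF (DN/65535 in the
# file's unit range, exact for integers); calibrated/ratio images as 32-bit
# float scaled into [0,1] by RR_TIFF_SCALE (documented in the vignette).

RR_TIFF_SCALE <- 8

write_frame_tiff <- function(pixels, path) {
  tiff::writeTIFF(pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

read_frame_tiff <- function(path) {
  if (!file.exists(path)) rw_stop("rw_io_error", "missing image file: %s", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    rw_stop("rw_format_error", "non-grayscale TIFF: %s", path)
  }
  round(img * 65535)
}

write_stack_tiff <- function(voxels, path) {
  slices <- lapply(seq_len(dim(voxels)[3]), function(z) voxels[, , z] / 65535)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

read_stack_tiff <- function(path) {
  if (!file.exists(path)) rw_stop("rw_io_error", "missing image file: %s", path)
  slices <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(slices[[1]])[1:2], length(slices)))
  for (z in seq_along(slices)) arr[, , z] <- round(slices[[z]] * 65535)
  arr
}

write_float_tiff <- function(values, path, scale = RR_TIFF_SCALE) {
  x <- values / scale
  x[!is.finite(x)] <- 0
  x[x < 0] <- 0
  x[x > 1] <- 1
  tiff::writeTIFF(x, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}
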