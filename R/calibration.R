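# Cuvette-reference calibration (in vivo) and flat-field correction plus
# background zeroing (cryo).

#' Cuvette reference intensity
#'
#' The mean intensity of a cuvette frame (a uniform fluorophore solution
#' imaged in the same channel on the same day as the tissue) is the
#' calibration divisor that cancels day-to-day excitation drift. The mean is
#' taken over all pixels of the cuvette frame.
#'
#' @param frame A cuvette [channel_frame()] (`NADH` or `FAD`).
#' @return Object of class `cuvette_reference` with fields `channel`,
#'   `mean_intensity`, `day`.
#' @export
cuvette_reference <- function(frame) {
  stopifnot(inherits(frame, "channel_frame"))
  if (!frame$channel %in% c("NADH", "FAD")) {
    rw_stop("rw_calibration_error",
            "cuvette references exist only for fluorescence channels (got %s)",
            frame$channel)
  }
  m <- mean(frame$pixels)
  if (m <= 0) rw_stop("rw_calibration_error", "cuvette mean intensity must be > 0")
  structure(list(channel = frame$channel, mean_intensity = m, day = frame$day),
            class = "cuvette_reference")
}

#' Load one in vivo session from a cohort manifest
#'
#' Reads the white-light, NADH and FAD tissue frames and the per-channel
#' cuvette frames of one subject-day, attaches metadata, and computes the
#' cuvette reference means. Frames must be 16-bit grayscale TIFFs with
#' values within the 14-bit camera range.
#'
#' @param manifest Manifest data frame (columns subject, group, day, channel,
#'   kind, path) as written by [simulate_cohort()].
#' @param dir Dataset directory the manifest paths are relative to.
#' @param subject,day Session to load.
#' @param pixel_size_um Pixel size to attach, micrometres.
#' @return List with `frames` (WHITE, NADH, FAD) and `refs` (NADH, FAD
#'   [cuvette_reference()]s).
#' @export
load_session <- function(manifest, dir, subject, day, pixel_size_um = 40) {
  rows <- manifest[manifest$subject == subject & manifest$day == day &
                     manifest$kind %in% c("tissue", "cuvette"), ]
  frames <- list()
  for (ch in CHANNELS) {
    r <- rows[rows$channel == ch & rows$kind == "tissue", ]
    if (nrow(r) != 1L) {
      rw_stop("rw_manifest_error",
              "session %s day %s: expected exactly one %s tissue frame, found %d",
              subject, day, ch, nrow(r))
    }
    px <- read_frame_tiff(file.path(dir, r$path))
    if (max(px) > MAX_DN) {
      rw_stop("rw_format_error", "%s frame exceeds 14-bit range: %s", ch, r$path)
    }
    n_sat <- sum(px >= MAX_DN)
    if (n_sat > 0.01 * length(px)) {
      warning(sprintf("session %s day %s: %.1f%% saturated pixels in %s frame",
                      subject, day, 100 * n_sat / length(px), ch))
    }
    frames[[ch]] <- channel_frame(px, ch, pixel_size_um, subject = subject,
                                  group = r$group, day = day)
  }
  refs <- list()
  for (ch in c("NADH", "FAD")) {
    r <- rows[rows$channel == ch & rows$kind == "cuvette", ]
    if (nrow(r) != 1L) {
      rw_stop("rw_manifest_error",
              "session %s day %s: missing %s cuvette frame", subject, day, ch)
    }
    px <- read_frame_tiff(file.path(dir, r$path))
    refs[[ch]] <- cuvette_reference(
      channel_frame(px, ch, pixel_size_um, subject = subject, day = day)
    )
  }
  list(frames = frames, refs = refs)
}

#' Load one cryo biopsy from a cohort manifest
#'
#' @inheritParams load_session
#' @param voxel_size_um Length-3 voxel size to attach.
#' @return List with `nadh` and `fad` [cryo_stack()]s, each carrying its
#'   flat-field frame.
#' @export
load_cryo <- function(manifest, dir, subject, day, voxel_size_um = c(40, 40, 40)) {
  rows <- manifest[manifest$subject == subject & manifest$day == day &
                     manifest$kind %in% c("stack", "flat"), ]
  out <- list()
  for (ch in c("NADH", "FAD")) {
    rs <- rows[rows$channel == ch & rows$kind == "stack", ]
    rf <- rows[rows$channel == ch & rows$kind == "flat", ]
    if (nrow(rs) != 1L || nrow(rf) != 1L) {
      rw_stop("rw_manifest_error",
              "biopsy %s day %s: missing %s stack or flat frame", subject, day, ch)
    }
    vox <- read_stack_tiff(file.path(dir, rs$path))
    flat <- read_frame_tiff(file.path(dir, rf$path))
    out[[tolower(ch)]] <- cryo_stack(vox, ch, voxel_size_um, flat_field = flat,
                                     subject = subject, group = rs$group,
                                     day = day)
  }
  out
}

#' Calibrate a fluorescence frame against its cuvette reference
#'
#' Divides every pixel by the cuvette mean intensity of the same channel and
#' day, yielding a dimensionless frame. Because the day's lamp drift
#' multiplies tissue and cuvette frames identically, the calibrated frame is
#' drift-free. Calibrating an already-calibrated frame is a contract
#' violation and errors.
#'
#' @param frame A raw [channel_frame()] (`NADH` or `FAD`).
#' @param ref The matching [cuvette_reference()].
#' @return The calibrated frame (flagged `calibrated = TRUE`).
#' @export
calibrate_frame <- function(frame, ref) {
  stopifnot(inherits(frame, "channel_frame"), inherits(ref, "cuvette_reference"))
  if (frame$calibrated) {
    rw_stop("rw_calibration_error", "frame is already calibrated")
  }
  if (frame$channel != ref$channel) {
    rw_stop("rw_calibration_error", "channel mismatch: frame %s vs reference %s",
            frame$channel, ref$channel)
  }
  if (ref$mean_intensity <= 0) {
    rw_stop("rw_calibration_error", "non-positive cuvette reference")
  }
  out <- frame
  out$pixels <- frame$pixels / ref$mean_intensity
  out$calibrated <- TRUE
  out
}

#' Flat-field correct a cryo stack
#'
#' Divides every slice element-wise by `flat_field / mean(flat_field)`. The
#' mean-normalized divisor removes the spatial illumination pattern while
#' preserving the stack's global mean scale.
#'
#' @param stack A [cryo_stack()] with a strictly positive flat field.
#' @return The corrected stack (flagged `flat_corrected = TRUE`).
#' @export
flat_field_correct <- function(stack) {
  stopifnot(inherits(stack, "cryo_stack"))
  if (is.null(stack$flat_field)) {
    rw_stop("rw_calibration_error", "stack has no flat-field frame")
  }
  if (any(stack$flat_field <= 0)) {
    rw_stop("rw_calibration_error", "flat field must be strictly positive")
  }
  if (stack$flat_corrected) {
    rw_stop("rw_calibration_error", "stack is already flat-field corrected")
  }
  divisor <- stack$flat_field / mean(stack$flat_field)
  out <- stack
  for (z in seq_len(dim(stack$voxels)[3])) {
    out$voxels[, , z] <- stack$voxels[, , z] / divisor
  }
  out$flat_corrected <- TRUE
  out
}

#' Zero the low-intensity background of a cryo stack
#'
#' Voxels below `threshold_fraction` times the stack's 99.5th-percentile
#' intensity are set to zero and marked background; they are excluded from
#' all downstream redox statistics. The percentile (rather than the maximum)
#' anchors the cutoff so isolated hot voxels cannot inflate it.
#'
#' @param stack A [cryo_stack()].
#' @param threshold_fraction Fraction in `[0, 1)` of the 99.5th percentile.
#' @return List with `stack` (background zeroed) and `background` (logical
#'   array marking zeroed voxels).
#' @export
zero_background <- function(stack, threshold_fraction = 0.10) {
  stopifnot(inherits(stack, "cryo_stack"))
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    rw_stop("rw_calibration_error",
            "threshold_fraction must be in [0, 1) (got %g)", threshold_fraction)
  }
  cutoff <- threshold_fraction *
    stats::quantile(stack$voxels, 0.995, names = FALSE)
  bg <- stack$voxels < cutoff
  out <- stack
  out$voxels[bg] <- 0
  out$background_zeroed <- TRUE
  list(stack = out, background = bg)
}
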