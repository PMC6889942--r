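#' Parameters of a synthetic wound-imaging cohort
#'
#' Bundles every setting of the synthetic-cohort generator: cohort layout
#' (group sizes, imaging days, biopsy days), wound geometry (a 10 mm circular
#' full-thickness wound imaged at 40 um/pixel), the planted group-level redox
#' trajectories, day-to-day excitation-lamp drift, and the camera noise model
#' (Poisson shot noise with gain plus Gaussian read noise, 14-bit range).
#'
#' The defaults encode the study conditions the pipeline is meant to recover:
#' both groups start at a surface redox ratio (RR) of 1.2 on day 0; controls
#' hold 1.2 while their wound closes (radius 5.0 -> 2.2 mm over 6 days);
#' diabetic wounds do not close (constant 5.0 mm radius) and their RR falls
#' 1.2 -> 0.468, a 61% drop by day 6. Volumetric truth for day-6 biopsies is
#' 1.2 (control) vs 0.408 (diabetic), a 66% difference; day-0 biopsies are
#' equal across groups.
#'
#' @param n_per_group Mice per group imaged in vivo at every day.
#' @param days In vivo imaging days post-wounding.
#' @param frame_shape Frame size in pixels (rows, cols). At 512x512 the full
#'   5 mm wound radius (125 px at 40 um) fits with margin; smaller frames use
#'   proportionally scaled geometry (see [geometry_scale()]), recorded in the
#'   ground truth.
#' @param pixel_size_um Pixel size, micrometres (constant across days).
#' @param wound_radius_mm_day0 Initial wound radius in mm (10 mm wound).
#' @param control_radius_schedule,diabetic_radius_schedule Named numeric
#'   vectors mapping day to wound radius (mm). Controls close monotonically;
#'   the diabetic schedule is constant by default.
#' @param rr_true Data frame (group, day, rr): planted group-mean surface RR.
#' @param rr_true_volumetric Data frame (group, day, rr): planted group-mean
#'   volumetric RR for biopsy days.
#' @param biopsy_n Named vector: biopsies per group at day 0 and day 6.
#'   Day-6 biopsies come from the in vivo animals; day-0 biopsies from
#'   additional animals sacrificed at wounding.
#' @param subject_effect_sd SD of the per-animal random offset shared by all
#'   of that animal's true RR values.
#' @param coupling_slope_b Slope (RR per unit normalized area) linking a
#'   subject's area deviation from its group-day schedule to its true RR;
#'   negative: larger-than-scheduled wounds are more oxidized.
#' @param coupling_target_r2 Target coefficient of determination used to set
#'   the per-observation RR noise SD from the closed form
#'   `sd^2 = b^2 * Var(A) * (1 - R2) / R2`, with `Var(A)` taken over the
#'   planted normalized-area schedules.
#' @param lamp_drift_sigma Lognormal sigma of the per-day, per-channel
#'   excitation intensity factor. The same factor multiplies the tissue frame
#'   and the same-day cuvette frame of a channel, which is what makes
#'   cuvette calibration cancel it.
#' @param noise Logical; apply the camera noise model. With `FALSE` frames
#'   hold exact (unrounded) mean intensities, used for exactness tests.
#' @param noise_gain Camera gain (DN per photoelectron) for the Poisson term.
#' @param read_noise_sd Gaussian read noise SD, DN.
#' @param bit_depth Camera bit depth; fixed at 14 (intensities in 0..16383).
#' @param stack_shape Cryo stack size in voxels (rows, cols, slices).
#' @param voxel_size_um Voxel size per axis, micrometres.
#' @param seed Integer master seed; the entire cohort is a deterministic
#'   function of it.
#'
#' @return An object of class `cohort_params`.
#' @seealso [simulate_cohort()], [cohort_truth()]
#' @export
cohort_params <- function(n_per_group = 6,
                          days = c(0, 2, 4, 6),
                          frame_shape = c(256, 256),
                          pixel_size_um = 40,
                          wound_radius_mm_day0 = 5,
                          control_radius_schedule = c("0" = 5, "2" = 4, "4" = 3, "6" = 2.2),
                          diabetic_radius_schedule = NULL,
                          rr_true = NULL,
                          rr_true_volumetric = NULL,
                          biopsy_n = c("0" = 4, "6" = 6),
                          subject_effect_sd = 0.03,
                          coupling_slope_b = -0.5,
                          coupling_target_r2 = 0.72,
                          lamp_drift_sigma = 0.15,
                          noise = TRUE,
                          noise_gain = 4,
                          read_noise_sd = 10,
                          bit_depth = 14,
                          stack_shape = c(96, 96, 32),
                          voxel_size_um = c(40, 40, 40),
                          seed = 1) {
  if (is.null(diabetic_radius_schedule)) {
    diabetic_radius_schedule <- stats::setNames(
      rep(wound_radius_mm_day0, length(days)), as.character(days)
    )
  }
  if (is.null(rr_true)) {
    rr_true <- data.frame(
      group = rep(c("control", "diabetic"), each = 4L),
      day   = rep(c(0, 2, 4, 6), 2L),
      rr    = c(1.2, 1.2, 1.2, 1.2,
                1.2, 0.80, 0.60, 0.468)
    )
  }
  if (is.null(rr_true_volumetric)) {
    rr_true_volumetric <- data.frame(
      group = rep(c("control", "diabetic"), each = 2L),
      day   = rep(c(0, 6), 2L),
      rr    = c(1.2, 1.2, 1.2, 0.408)
    )
  }
  p <- structure(list(
    n_per_group = as.integer(n_per_group),
    days = as.numeric(days),
    frame_shape = as.integer(frame_shape),
    pixel_size_um = pixel_size_um,
    wound_radius_mm_day0 = wound_radius_mm_day0,
    control_radius_schedule = control_radius_schedule,
    diabetic_radius_schedule = diabetic_radius_schedule,
    rr_true = rr_true,
    rr_true_volumetric = rr_true_volumetric,
    biopsy_n = biopsy_n,
    subject_effect_sd = subject_effect_sd,
    coupling_slope_b = coupling_slope_b,
    coupling_target_r2 = coupling_target_r2,
    lamp_drift_sigma = lamp_drift_sigma,
    noise = isTRUE(noise),
    noise_gain = noise_gain,
    read_noise_sd = read_noise_sd,
    bit_depth = as.integer(bit_depth),
    stack_shape = as.integer(stack_shape),
    voxel_size_um = voxel_size_um,
    seed = as.integer(seed)
  ), class = "cohort_params")
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  if (p$bit_depth != 14L) {
    rw_stop("rw_param_error", "bit_depth is fixed at 14 (got %d)", p$bit_depth)
  }
  if (p$n_per_group < 1L) {
    rw_stop("rw_param_error", "n_per_group must be >= 1 (got %d)", p$n_per_group)
  }
  if (!0 %in% p$days) rw_stop("rw_param_error", "days must include day 0")
  if (length(p$frame_shape) != 2L || any(p$frame_shape < 16L)) {
    rw_stop("rw_param_error", "frame_shape must be two dimensions >= 16 px")
  }
  if (p$pixel_size_um <= 0) rw_stop("rw_param_error", "pixel_size_um must be > 0")
  for (nm in c("control_radius_schedule", "diabetic_radius_schedule")) {
    sched <- p[[nm]]
    if (!all(as.character(p$days) %in% names(sched))) {
      rw_stop("rw_param_error", "%s must cover every imaging day", nm)
    }
    if (any(sched <= 0)) rw_stop("rw_param_error", "%s has non-positive radii", nm)
  }
  half_extent_mm <- min(p$frame_shape) / 2 * p$pixel_size_um / 1000 / geometry_scale(p)
  if (any(c(p$control_radius_schedule, p$diabetic_radius_schedule) > half_extent_mm)) {
    rw_stop("rw_param_error",
            "wound radius exceeds the frame half-extent (%.2f mm)", half_extent_mm)
  }
  ctrl <- p$control_radius_schedule[as.character(sort(p$days))]
  if (any(diff(ctrl) > 1e-12)) {
    rw_stop("rw_param_error", "control radius schedule must be non-increasing")
  }
  if (any(p$rr_true$rr <= 0) || any(p$rr_true_volumetric$rr <= 0)) {
    rw_stop("rw_param_error", "all planted redox ratios must be > 0")
  }
  invisible(p)
}

#' Geometry scale of a cohort relative to full-scale acquisition
#'
#' Full-scale geometry holds a 125 px wound radius (5 mm at 40 um/pixel),
#' which requires at least a 512x512 frame. Smaller frames shrink all
#' planted radii by `min(frame)/512` so the wound keeps the same relative
#' footprint; the scale is recorded in the ground truth.
#'
#' @param params A [cohort_params()] object.
#' @return Scalar scale factor in (0, 1].
#' @export
geometry_scale <- function(params) {
  min(1, min(params$frame_shape) / 512)
}

# Scheduled wound radius in pixels for a group and day.
radius_px <- function(params, group, day) {
  sched <- if (group == "control") params$control_radius_schedule
           else params$diabetic_radius_schedule
  r_mm <- unname(sched[as.character(day)])
  r_mm * 1000 / params$pixel_size_um * geometry_scale(params)
}

# Planted normalized-area schedule (continuous, (r_t/r_0)^2) per group-day.
area_schedule <- function(params) {
  out <- expand.grid(group = c("control", "diabetic"), day = params$days,
                     stringsAsFactors = FALSE)
  out$area <- vapply(seq_len(nrow(out)), function(i) {
    sched <- if (out$group[i] == "control") params$control_radius_schedule
             else params$diabetic_radius_schedule
    (unname(sched[as.character(out$day[i])]) / unname(sched[as.character(0)]))^2
  }, numeric(1))
  out
}

#' Per-observation RR noise SD implied by the area-coupling closed form
#'
#' The generator draws an independent noise term for every subject-day true
#' surface RR with SD `|b| * sqrt(Var(A) * (1 - R2) / R2)`, where `b` is the
#' area-coupling slope, `R2` the target coefficient of determination and
#' `Var(A)` the population variance of the planted normalized-area schedule
#' pooled over all group-day cells.
#'
#' @param params A [cohort_params()] object.
#' @return Scalar standard deviation.
#' @export
coupling_noise_sd <- function(params) {
  a <- area_schedule(params)$area
  var_a <- mean((a - mean(a))^2)
  r2 <- params$coupling_target_r2
  abs(params$coupling_slope_b) * sqrt(var_a * (1 - r2) / r2)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic wound cohort parameters\n")
  cat(sprintf("  %d mice/group, days {%s}, frames %dx%d @ %g um/px (scale %.2f)\n",
              x$n_per_group, paste(x$days, collapse = ","),
              x$frame_shape[1], x$frame_shape[2], x$pixel_size_um,
              geometry_scale(x)))
  cat(sprintf("  noise: %s (gain %g, read %g DN), lamp drift sigma %g, seed %d\n",
              if (x$noise) "on" else "off", x$noise_gain, x$read_noise_sd,
              x$lamp_drift_sigma, x$seed))
  invisible(x)
}
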