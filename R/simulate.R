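# Synthetic acquisition: renders in vivo sessions and cryo stacks from the
# planted ground truth.

# Fixed scene intensities (mean DN before lamp drift and noise). The wound
# bed emits FAD at WOUND_FAD_DN and NADH at rr_true * WOUND_FAD_DN so the
# calibrated pixel ratio equals the planted RR; shaved skin has a distinct
# white-light albedo so the white channel is cleanly bimodal.
WOUND_FAD_DN   <- 1000
SKIN_NADH_DN   <- 400
SKIN_FAD_DN    <- 350
WHITE_LEVEL_DN <- 8000
WOUND_ALBEDO   <- 0.3
SKIN_ALBEDO    <- 0.8
CUVETTE_DN     <- c(NADH = 1000, FAD = 1000)
CRYO_BG_DN     <- 30
CRYO_FLAT_DN   <- 8000

# Per-day per-channel excitation drift factor (lognormal, shared by every
# session acquired that day, and by tissue and cuvette frames alike).
lamp_drift <- function(params, day, channel) {
  if (params$lamp_drift_sigma <= 0) return(1)
  with_rng(rw_subseed(params$seed, "drift", day, channel),
           stats::rlnorm(1, 0, params$lamp_drift_sigma))
}

# Poisson shot noise (with camera gain) plus Gaussian read noise, rounded
# and clipped to the 14-bit range.
apply_camera_noise <- function(x, params, seed) {
  with_rng(seed, {
    y <- stats::rpois(length(x), lambda = as.vector(x) / params$noise_gain) *
      params$noise_gain +
      stats::rnorm(length(x), 0, params$read_noise_sd)
    y <- round(pmin(pmax(y, 0), MAX_DN))
    array(y, dim = dim(x))
  })
}

render_frame <- function(mean_img, params, channel, subject, day, kind) {
  px <- mean_img
  if (params$noise) {
    px <- apply_camera_noise(px, params,
                             rw_subseed(params$seed, "noise", subject, day,
                                        channel, kind))
  } else {
    px <- pmin(px, MAX_DN)
  }
  channel_frame(px, channel, params$pixel_size_um,
                subject = subject, day = day)
}

#' Simulate one in vivo imaging session
#'
#' Renders the white-light, NADH and FAD frames of one subject on one day,
#' together with the same-day cuvette reference frames. The wound is a filled
#' disk at the scheduled radius (centre jittered by up to 2 px); inside it
#' the mean NADH/FAD intensities encode the subject-day true surface RR, and
#' the day's lamp-drift factor multiplies both the tissue frame and the
#' cuvette frame of each fluorescence channel, so cuvette calibration cancels
#' it exactly.
#'
#' @param params A [cohort_params()] object.
#' @param subject Subject id (must exist in [cohort_subjects()]).
#' @param day Imaging day (must be in `params$days`).
#' @return List with elements `white`, `nadh`, `fad` ([channel_frame()]s),
#'   `cuvettes` (list `NADH`, `FAD`) and `truth` (the planted geometry and
#'   RR for this session).
#' @export
simulate_session <- function(params, subject, day) {
  if (!day %in% params$days) {
    rw_stop("rw_schedule_error", "day %s is not in the imaging schedule {%s}",
            day, paste(params$days, collapse = ","))
  }
  subj <- cohort_subjects(params)
  hit <- subj$subject == subject & subj$in_vivo
  if (!any(hit)) {
    rw_stop("rw_schedule_error", "subject %s is not in the in vivo cohort", subject)
  }
  group <- subj$group[hit][1]

  r <- radius_px(params, group, day)
  ctr <- wound_center(params, subject, day)
  disk <- disk_mask(params$frame_shape, ctr, r)
  rr <- true_surface_rr(params, subject, group, day)

  nadh_mean <- ifelse(disk, rr * WOUND_FAD_DN, SKIN_NADH_DN)
  fad_mean  <- ifelse(disk, WOUND_FAD_DN, SKIN_FAD_DN)
  white_mean <- ifelse(disk, WOUND_ALBEDO, SKIN_ALBEDO) * WHITE_LEVEL_DN

  drift <- vapply(CHANNELS, function(ch) lamp_drift(params, day, ch), numeric(1))

  white <- render_frame(white_mean * drift["WHITE"], params, "WHITE", subject, day, "tissue")
  nadh  <- render_frame(nadh_mean * drift["NADH"], params, "NADH", subject, day, "tissue")
  fad   <- render_frame(fad_mean * drift["FAD"], params, "FAD", subject, day, "tissue")

  cuv <- lapply(c("NADH", "FAD"), function(ch) {
    cm <- matrix(CUVETTE_DN[ch] * drift[ch],
                 params$frame_shape[1], params$frame_shape[2])
    render_frame(cm, params, ch, subject, day, "cuvette")
  })
  names(cuv) <- c("NADH", "FAD")

  truth <- list(subject = subject, group = group, day = day,
                radius_px = r, center = ctr, n_pixels_true = sum(disk),
                rr_true = rr, mask_true = disk)
  list(white = white, nadh = nadh, fad = fad, cuvettes = cuv, truth = truth)
}

# Cylinder-plus-cap wound phantom inside the tissue block: a vertical
# cylinder from the surface down, finished by a hemispherical cap.
cryo_phantom_mask <- function(shape, center_rc, radius, depth) {
  dr <- (seq_len(shape[1]) - center_rc[1])^2
  dc <- (seq_len(shape[2]) - center_rc[2])^2
  rho2 <- outer(dr, dc, "+")
  mask <- array(FALSE, dim = shape)
  for (z in seq_len(shape[3])) {
    if (z <= depth) {
      mask[, , z] <- rho2 <= radius^2
    } else {
      rem2 <- radius^2 - (z - depth)^2
      if (rem2 > 0) mask[, , z] <- rho2 <= rem2
    }
  }
  mask
}

# Smooth multiplicative illumination field: radial falloff to 70% at the
# frame corners.
cryo_flat_pattern <- function(shape) {
  ctr <- (shape[1:2] + 1) / 2
  dr <- (seq_len(shape[1]) - ctr[1])^2
  dc <- (seq_len(shape[2]) - ctr[2])^2
  rho2 <- outer(dr, dc, "+")
  1 - 0.3 * rho2 / max(rho2)
}

#' Simulate one cryo-imaging biopsy
#'
#' Renders the 3D NADH and FAD volumes of a flash-frozen wound biopsy: a
#' cylinder-plus-cap wound phantom in a low-intensity tissue block, with the
#' voxelwise NADH/FAD ratio equal to the subject's true volumetric RR, a
#' smooth illumination falloff applied identically to every slice, and the
#' matching flat-field frames emitted for correction.
#'
#' @param params A [cohort_params()] object.
#' @param subject Subject id in the biopsy roster.
#' @param day Biopsy day; only 0 and 6 are scheduled.
#' @return List with `nadh`, `fad` ([cryo_stack()]s carrying their flat
#'   fields), `flats` (list of flat-field frames in DN) and `truth`.
#' @export
simulate_cryo_stack <- function(params, subject, day) {
  if (!day %in% c(0, 6)) {
    rw_stop("rw_schedule_error",
            "biopsies are scheduled only at days 0 and 6 (got %s)", day)
  }
  roster <- biopsy_roster(params)
  hit <- roster$subject == subject & roster$day == day
  if (!any(hit)) {
    rw_stop("rw_schedule_error", "subject %s has no day-%s biopsy", subject, day)
  }
  group <- roster$group[hit][1]
  rr <- true_volumetric_rr(params, subject, group, day)

  shape <- params$stack_shape
  radius <- 0.2 * min(shape[1:2])
  depth <- round(0.375 * shape[3])
  jit <- with_rng(rw_subseed(params$seed, "cryo-jitter", subject, day),
                  sample(-2:2, 2, replace = TRUE))
  ctr <- round((shape[1:2] + 1) / 2) + jit
  phantom <- cryo_phantom_mask(shape, ctr, radius, depth)

  # FAD carries a mild axial intensity gradient; NADH = rr * FAD voxelwise,
  # so the ratio (and hence the volume mean) is exactly rr.
  z_gain <- 0.9 + 0.2 * (seq_len(shape[3]) - 1) / max(shape[3] - 1, 1)
  fad_mean <- array(CRYO_BG_DN, dim = shape)
  nadh_mean <- array(CRYO_BG_DN, dim = shape)
  for (z in seq_len(shape[3])) {
    sl <- phantom[, , z]
    f <- fad_mean[, , z]
    f[sl] <- WOUND_FAD_DN * z_gain[z]
    fad_mean[, , z] <- f
    n <- nadh_mean[, , z]
    n[sl] <- rr * WOUND_FAD_DN * z_gain[z]
    nadh_mean[, , z] <- n
  }

  flat <- cryo_flat_pattern(shape)
  for (z in seq_len(shape[3])) {
    fad_mean[, , z] <- fad_mean[, , z] * flat
    nadh_mean[, , z] <- nadh_mean[, , z] * flat
  }

  render_stack <- function(mean_vol, channel) {
    v <- mean_vol
    if (params$noise) {
      v <- apply_camera_noise(v, params,
                              rw_subseed(params$seed, "noise", subject, day,
                                         channel, "stack"))
    }
    v
  }
  render_flat <- function(channel) {
    fm <- flat * CRYO_FLAT_DN
    if (params$noise) {
      fm <- apply_camera_noise(fm, params,
                               rw_subseed(params$seed, "noise", subject, day,
                                          channel, "flat"))
      fm[fm < 1] <- 1  # flat fields must stay strictly positive
    }
    fm
  }

  flats <- list(NADH = render_flat("NADH"), FAD = render_flat("FAD"))
  nadh <- cryo_stack(render_stack(nadh_mean, "NADH"), "NADH",
                     params$voxel_size_um, flat_field = flats$NADH,
                     subject = subject, group = group, day = day)
  fad <- cryo_stack(render_stack(fad_mean, "FAD"), "FAD",
                    params$voxel_size_um, flat_field = flats$FAD,
                    subject = subject, group = group, day = day)

  truth <- list(subject = subject, group = group, day = day,
                rr_true = rr, n_voxels_true = sum(phantom),
                mask_true = phantom)
  list(nadh = nadh, fad = fad, flats = flats, truth = truth)
}

#' Simulate a full cohort to disk
#'
#' Writes one directory per subject-day containing 16-bit grayscale TIFF
#' frames (white light, NADH, FAD, and per-channel cuvette references) for
#' every in vivo session, multi-page TIFF stacks plus flat-field frames for
#' every biopsy, a manifest CSV listing every file, and the machine-readable
#' ground-truth sidecar (`truth.json`).
#'
#' @param params A [cohort_params()] object.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly. Side effects: files under
#'   `out_dir`.
#' @export
simulate_cohort <- function(params, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rw_stop("rw_io_error", "cannot create output directory %s", out_dir)
  }
  subj <- cohort_subjects(params)
  invivo <- subj[subj$in_vivo, ]
  manifest <- list()

  add_row <- function(subject, group, day, channel, kind, path) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      subject = subject, group = group, day = day,
      channel = channel, kind = kind, path = path
    )
  }

  for (i in seq_len(nrow(invivo))) {
    for (day in params$days) {
      s <- invivo$subject[i]
      g <- invivo$group[i]
      ses <- simulate_session(params, s, day)
      sdir <- sprintf("%s_d%g", s, day)
      dir.create(file.path(out_dir, sdir), showWarnings = FALSE)
      frames <- list(WHITE = ses$white, NADH = ses$nadh, FAD = ses$fad)
      for (ch in names(frames)) {
        rel <- file.path(sdir, sprintf("%s.tif", tolower(ch)))
        write_frame_tiff(round(frames[[ch]]$pixels), file.path(out_dir, rel))
        add_row(s, g, day, ch, "tissue", rel)
      }
      for (ch in c("NADH", "FAD")) {
        rel <- file.path(sdir, sprintf("cuvette_%s.tif", tolower(ch)))
        write_frame_tiff(round(ses$cuvettes[[ch]]$pixels), file.path(out_dir, rel))
        add_row(s, g, day, ch, "cuvette", rel)
      }
    }
  }

  roster <- biopsy_roster(params)
  for (k in seq_len(nrow(roster))) {
    s <- roster$subject[k]; g <- roster$group[k]; day <- roster$day[k]
    bio <- simulate_cryo_stack(params, s, day)
    sdir <- sprintf("%s_d%g_cryo", s, day)
    dir.create(file.path(out_dir, sdir), showWarnings = FALSE)
    for (ch in c("NADH", "FAD")) {
      st <- if (ch == "NADH") bio$nadh else bio$fad
      rel <- file.path(sdir, sprintf("%s_stack.tif", tolower(ch)))
      write_stack_tiff(round(st$voxels), file.path(out_dir, rel))
      add_row(s, g, day, ch, "stack", rel)
      relf <- file.path(sdir, sprintf("flat_%s.tif", tolower(ch)))
      write_frame_tiff(round(bio$flats[[ch]]), file.path(out_dir, relf))
      add_row(s, g, day, ch, "flat", relf)
    }
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  truth <- cohort_truth(params)
  truth$surface$subject <- as.character(truth$surface$subject)
  jsonlite::write_json(
    list(geometry_scale = truth$geometry_scale,
         pixel_size_um = params$pixel_size_um,
         seed = params$seed,
         surface = truth$surface,
         volumetric = truth$volumetric),
    file.path(out_dir, "truth.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE
  )
  invisible(manifest)
}
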