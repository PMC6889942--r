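# Ground-truth construction: the planted "answers" the pipeline must recover.

#' Subjects of a synthetic cohort
#'
#' Control animals are `C01..`, diabetic `D01..`. The first `n_per_group`
#' of each group are imaged in vivo on every day (and biopsied at day 6);
#' additional animals (suffix numbers above `n_per_group`) exist only as
#' day-0 biopsies.
#'
#' @param params A [cohort_params()] object.
#' @return Data frame with columns subject, group, in_vivo (logical).
#' @export
cohort_subjects <- function(params) {
  n_day0 <- unname(params$biopsy_n["0"])
  make <- function(prefix, group) {
    n_tot <- params$n_per_group + n_day0
    data.frame(
      subject = sprintf("%s%02d", prefix, seq_len(n_tot)),
      group = group,
      in_vivo = seq_len(n_tot) <= params$n_per_group
    )
  }
  rbind(make("C", "control"), make("D", "diabetic"))
}

# Biopsy roster: (subject, group, day) rows for the cryo arm.
biopsy_roster <- function(params) {
  subj <- cohort_subjects(params)
  n0 <- unname(params$biopsy_n["0"])
  n6 <- min(unname(params$biopsy_n["6"]), params$n_per_group)
  rows <- lapply(c("control", "diabetic"), function(g) {
    sg <- subj[subj$group == g, ]
    day0 <- sg[!sg$in_vivo, ][seq_len(n0), ]
    day6 <- sg[sg$in_vivo, ][seq_len(n6), ]
    rbind(
      data.frame(subject = day0$subject, group = g, day = 0),
      data.frame(subject = day6$subject, group = g, day = 6)
    )
  })
  do.call(rbind, rows)
}

subject_effect <- function(params, subject) {
  with_rng(rw_subseed(params$seed, "subj", subject),
           stats::rnorm(1, 0, params$subject_effect_sd))
}

rr_noise <- function(params, subject, day) {
  with_rng(rw_subseed(params$seed, "eps", subject, day),
           stats::rnorm(1, 0, coupling_noise_sd(params)))
}

group_mean_rr <- function(params, group, day, volumetric = FALSE) {
  tab <- if (volumetric) params$rr_true_volumetric else params$rr_true
  hit <- tab$group == group & tab$day == day
  if (!any(hit)) {
    rw_stop("rw_schedule_error", "no planted RR for group %s, day %s", group, day)
  }
  tab$rr[hit][1]
}

# True surface RR for one subject-day: group-day mean + animal offset +
# area-coupling term + independent noise. The coupling is centred on the
# group-day area schedule, so under default schedules (where every subject's
# true area equals its schedule) it is exactly zero and the planted group
# trajectories are preserved.
true_surface_rr <- function(params, subject, group, day, area = NULL) {
  sched <- area_schedule(params)
  a_sched <- sched$area[sched$group == group & sched$day == day]
  a <- area %||% a_sched
  rr <- group_mean_rr(params, group, day) +
    subject_effect(params, subject) +
    params$coupling_slope_b * (a - a_sched) +
    rr_noise(params, subject, day)
  max(rr, 0.05)
}

true_volumetric_rr <- function(params, subject, group, day) {
  max(group_mean_rr(params, group, day, volumetric = TRUE) +
        subject_effect(params, subject), 0.05)
}

# Jittered integer wound centre for a session (translation leaves the
# lattice pixel count unchanged).
wound_center <- function(params, subject, day) {
  ctr <- (params$frame_shape + 1) / 2
  jit <- with_rng(rw_subseed(params$seed, "jitter", subject, day),
                  sample(-2:2, 2, replace = TRUE))
  round(ctr) + jit
}

#' Pixels inside a disk
#'
#' Logical matrix marking pixel centres whose Euclidean distance from
#' `center` is at most `radius` (pixel units, inclusive boundary).
#'
#' @param shape Frame dimensions (rows, cols).
#' @param center Disk centre (row, col), pixel-centre coordinates.
#' @param radius Radius in pixels.
#' @return Logical matrix of dimension `shape`.
#' @export
disk_mask <- function(shape, center, radius) {
  dr <- (seq_len(shape[1]) - center[1])^2
  dc <- (seq_len(shape[2]) - center[2])^2
  outer(dr, dc, "+") <= radius^2
}

#' Ground truth of a synthetic cohort
#'
#' Computes, in closed form, everything the generator plants: per subject-day
#' the true wound geometry (centre, radius, exact pixel count), true
#' normalized area (pixel count relative to the subject's day 0) and true
#' surface RR; and per biopsy the true volumetric RR. Purely a function of
#' the parameters (including the seed) - no images are rendered.
#'
#' @param params A [cohort_params()] object.
#' @return List with elements `surface` (data frame), `volumetric`
#'   (data frame) and `geometry_scale`.
#' @export
cohort_truth <- function(params) {
  subj <- cohort_subjects(params)
  invivo <- subj[subj$in_vivo, ]
  grid <- expand.grid(i = seq_len(nrow(invivo)), day = params$days)
  surface <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    s <- invivo[grid$i[k], ]
    day <- grid$day[k]
    r <- radius_px(params, s$group, day)
    ctr <- wound_center(params, s$subject, day)
    n_px <- sum(disk_mask(params$frame_shape, ctr, r))
    data.frame(
      subject = s$subject, group = s$group, day = day,
      radius_px = r, center_row = ctr[1], center_col = ctr[2],
      n_pixels_true = n_px,
      rr_true = true_surface_rr(params, s$subject, s$group, day)
    )
  }))
  n0 <- surface$n_pixels_true[surface$day == 0]
  names(n0) <- surface$subject[surface$day == 0]
  surface$area_true <- surface$n_pixels_true / n0[surface$subject]

  biopsy <- biopsy_roster(params)
  biopsy$rr_true <- vapply(seq_len(nrow(biopsy)), function(k) {
    true_volumetric_rr(params, biopsy$subject[k], biopsy$group[k], biopsy$day[k])
  }, numeric(1))

  list(surface = surface, volumetric = biopsy,
       geometry_scale = geometry_scale(params))
}
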