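# The generator: geometry, planted truth, determinism, noise/drift model.

test_that("disk pixel count matches the exhaustive lattice oracle", {
  # full-scale wound: 5 mm radius at 40 um/pixel = 125 px
  r <- 125
  ctr <- c(256, 256)
  mask <- disk_mask(c(512, 512), ctr, r)
  oracle <- 0L
  for (i in seq_len(512)) {
    d2 <- (i - ctr[1])^2 + (seq_len(512) - ctr[2])^2
    oracle <- oracle + sum(d2 <= r^2)
  }
  expect_identical(sum(mask), oracle)
  expect_identical(oracle, 49077L)

  # translation invariance and smaller radii
  for (r in c(10.5, 31, 62.5)) {
    m1 <- disk_mask(c(140, 140), c(70, 70), r)
    m2 <- disk_mask(c(140, 140), c(68, 73), r)
    expect_identical(sum(m1), sum(m2))
  }
})

test_that("same session rendered twice is bit-identical and leaves the RNG alone", {
  p <- tiny_params()
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_session(p, "C01", 2)
  expect_identical(.Random.seed, before)
  s2 <- simulate_session(p, "C01", 2)
  expect_identical(s1$nadh$pixels, s2$nadh$pixels)
  expect_identical(s1$white$pixels, s2$white$pixels)
  expect_identical(s1$cuvettes$FAD$pixels, s2$cuvettes$FAD$pixels)
})

test_that("noise- and drift-free uniform wound yields an exactly flat calibrated ratio", {
  rr2 <- data.frame(group = rep(c("control", "diabetic"), each = 4),
                    day = rep(c(0, 2, 4, 6), 2), rr = 2)
  p <- quiet_params(rr_true = rr2, subject_effect_sd = 0, coupling_slope_b = 0)
  ses <- simulate_session(p, "D01", 0)
  nadh <- calibrate_frame(ses$nadh, cuvette_reference(ses$cuvettes$NADH))
  fad <- calibrate_frame(ses$fad, cuvette_reference(ses$cuvettes$FAD))
  ratio <- nadh$pixels / fad$pixels
  expect_equal(unique(as.vector(ratio[ses$truth$mask_true])), 2.0)
})

test_that("stored truth matches brute-force recomputation from noise-free mean images", {
  p <- quiet_params(lamp_drift_sigma = 0.2)  # drift on, noise off
  truth <- cohort_truth(p)
  for (k in sample(nrow(truth$surface), 4)) {
    row <- truth$surface[k, ]
    ses <- simulate_session(p, row$subject, row$day)
    nadh <- calibrate_frame(ses$nadh, cuvette_reference(ses$cuvettes$NADH))
    fad <- calibrate_frame(ses$fad, cuvette_reference(ses$cuvettes$FAD))
    manual <- mean(nadh$pixels[ses$truth$mask_true] /
                     fad$pixels[ses$truth$mask_true])
    expect_equal(manual, row$rr_true, tolerance = 1e-9)
    expect_identical(sum(ses$truth$mask_true), row$n_pixels_true)
  }
})

test_that("lamp drift cancels exactly after cuvette calibration", {
  base <- quiet_params()
  drifted <- quiet_params(lamp_drift_sigma = 0.4)
  for (day in c(0, 6)) {
    s0 <- simulate_session(base, "D02", day)
    s1 <- simulate_session(drifted, "D02", day)
    expect_false(isTRUE(all.equal(s0$nadh$pixels, s1$nadh$pixels)))
    c0 <- calibrate_frame(s0$nadh, cuvette_reference(s0$cuvettes$NADH))
    c1 <- calibrate_frame(s1$nadh, cuvette_reference(s1$cuvettes$NADH))
    expect_equal(c0$pixels, c1$pixels, tolerance = 1e-12)
  }
})

test_that("truth tables encode the planted study design", {
  p <- cohort_params(seed = 7)  # defaults: n=6/group, 256x256
  truth <- cohort_truth(p)
  surf <- truth$surface
  # day-0 normalized area is exactly 1 for every subject
  expect_true(all(surf$area_true[surf$day == 0] == 1))
  # control areas non-increasing, diabetic constant at 1
  for (s in unique(surf$subject)) {
    a <- surf$area_true[surf$subject == s][order(surf$day[surf$subject == s])]
    g <- surf$group[surf$subject == s][1]
    if (g == "control") expect_true(all(diff(a) <= 0))
    else expect_true(all(a == 1))
  }
  # biopsy roster: 4/group at day 0, 6/group at day 6
  vol <- truth$volumetric
  expect_equal(unname(table(vol$group, vol$day)["control", ]), c(4, 6))
  expect_equal(unname(table(vol$group, vol$day)["diabetic", ]), c(4, 6))
})

test_that("planted diabetic decline reproduces the configured fractional drop", {
  # with animal and observation noise silenced the group means are exact
  p <- quiet_params(subject_effect_sd = 0, coupling_slope_b = 0)
  truth <- cohort_truth(p)$surface
  m <- tapply(truth$rr_true, list(truth$group, truth$day), mean)
  expect_equal(1 - m["diabetic", "6"] / m["diabetic", "0"], 0.61, tolerance = 1e-12)
  expect_equal(unname(m["control", ]), rep(1.2, 4))
  # with default noise the configured drop is recovered approximately
  pd <- cohort_params(seed = 11)
  td <- cohort_truth(pd)$surface
  md <- tapply(td$rr_true, list(td$group, td$day), mean)
  expect_lt(abs((1 - md["diabetic", "6"] / md["diabetic", "0"]) - 0.61), 0.12)
})

test_that("cryo phantom truth matches a brute-force voxel count and ratio", {
  p <- quiet_params()
  bio <- simulate_cryo_stack(p, "C01", 6)
  # exhaustive voxel recount of the cylinder-plus-cap phantom
  shape <- dim(bio$truth$mask_true)
  oracle <- 0L
  for (z in seq_len(shape[3])) oracle <- oracle + sum(bio$truth$mask_true[, , z])
  expect_identical(bio$truth$n_voxels_true, oracle)
  expect_gt(oracle, 0)
  # noise-free ratio over true wound voxels equals the planted volumetric RR,
  # with or without flat-field correction (the field multiplies both channels)
  ratio_raw <- bio$nadh$voxels[bio$truth$mask_true] /
    bio$fad$voxels[bio$truth$mask_true]
  expect_equal(mean(ratio_raw), bio$truth$rr_true, tolerance = 1e-9)
  cn <- flat_field_correct(bio$nadh)
  cf <- flat_field_correct(bio$fad)
  ratio_cor <- cn$voxels[bio$truth$mask_true] / cf$voxels[bio$truth$mask_true]
  expect_equal(mean(ratio_cor), mean(ratio_raw), tolerance = 1e-6)
})

test_that("out-of-schedule requests raise schedule errors", {
  p <- tiny_params()
  expect_error(simulate_session(p, "C01", 3), class = "rw_schedule_error")
  expect_error(simulate_session(p, "ZZZ", 0), class = "rw_schedule_error")
  expect_error(simulate_cryo_stack(p, "C01", 2), class = "rw_schedule_error")
  expect_error(cohort_params(bit_depth = 12), class = "rw_param_error")
  expect_error(cohort_params(n_per_group = 0), class = "rw_param_error")
  expect_error(
    cohort_params(control_radius_schedule = c("0" = 3, "2" = 4, "4" = 3, "6" = 2)),
    class = "rw_param_error")
})

test_that("simulated cohorts on disk are deterministic with matching manifests", {
  p <- tiny_params(days = c(0, 6), biopsy_n = c("0" = 1, "6" = 1))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_cohort(p, d1)
  m2 <- simulate_cohort(p, d2)
  expect_identical(m1[setdiff(names(m1), "path")], m2[setdiff(names(m2), "path")])
  # file-level manifest size: sessions x 5 frames + biopsies x 4 files
  n_sessions <- p$n_per_group * 2 * length(p$days)
  n_biopsies <- 2 * 2  # 1 per group per endpoint day
  expect_equal(nrow(m1), n_sessions * 5 + n_biopsies * 4)
  expect_identical(readLines(file.path(d1, "truth.json")),
                   readLines(file.path(d2, "truth.json")))
})
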