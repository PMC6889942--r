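# End-to-end workflow: simulate a cohort, analyze every session and biopsy,
# and render the report. These functions back the `redoxwound` command-line
# script (inst/cli/redoxwound).

#' Run configuration
#'
#' Resolved settings of a pipeline run. `params` holds generator arguments
#' (passed to [cohort_params()]); the remaining fields control analysis.
#'
#' @param dataset_dir Directory holding (or receiving) the cohort dataset.
#' @param out_dir Directory for analysis outputs.
#' @param params Named list of [cohort_params()] arguments.
#' @param segmentation `"auto"` (white-light Otsu pipeline) or `"manual"`
#'   (masks listed in the manifest with kind `mask`).
#' @param fad_floor FAD floor for [redox_map()] (`NULL` = 1% of masked median).
#' @param threshold_fraction Background-zeroing fraction for the cryo arm.
#' @param hist_bins,hist_range Redox histogram layout.
#' @param save_maps Write per-session redox maps as scaled float TIFFs.
#' @param seed Seed override for `params`.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(dataset_dir = "dataset", out_dir = "analysis",
                       params = list(), segmentation = c("auto", "manual"),
                       fad_floor = NULL, threshold_fraction = 0.10,
                       hist_bins = 100, hist_range = c(0, 4),
                       save_maps = FALSE, seed = NULL) {
  segmentation <- match.arg(segmentation)
  if (!is.null(seed)) params$seed <- seed
  cfg <- structure(list(dataset_dir = dataset_dir, out_dir = out_dir,
                        params = params, segmentation = segmentation,
                        fad_floor = fad_floor,
                        threshold_fraction = threshold_fraction,
                        hist_bins = hist_bins, hist_range = hist_range,
                        save_maps = isTRUE(save_maps)),
                   class = "run_config")
  if (cfg$threshold_fraction < 0 || cfg$threshold_fraction >= 1) {
    rw_stop("rw_param_error", "threshold_fraction must be in [0, 1)")
  }
  if (cfg$hist_bins < 1 || cfg$hist_range[1] >= cfg$hist_range[2]) {
    rw_stop("rw_param_error", "invalid histogram settings")
  }
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) rw_stop("rw_io_error", "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  raw$hist_range <- unlist(raw$hist_range %||% c(0, 4))
  do.call(run_config, raw)
}

write_resolved_config <- function(config, dir) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
}

#' Simulate a cohort dataset (pipeline step)
#'
#' Builds [cohort_params()] from the configuration, writes the full dataset
#' (frames, stacks, manifest, ground truth) under `dataset_dir`, and stores
#' the resolved configuration beside it.
#'
#' @param config A [run_config()].
#' @return The manifest data frame, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  params <- do.call(cohort_params, config$params)
  manifest <- simulate_cohort(params, config$dataset_dir)
  write_resolved_config(config, config$dataset_dir)
  invisible(manifest)
}

analyze_one_session <- function(manifest, dir, subject, day, config) {
  ses <- load_session(manifest, dir, subject, day)
  mask <- if (config$segmentation == "auto") {
    segment_wound(ses$frames$WHITE)
  } else {
    row <- manifest[manifest$subject == subject & manifest$day == day &
                      manifest$kind == "mask", ]
    if (nrow(row) != 1L) {
      rw_stop("rw_mask_error", "no manual mask listed for %s day %s", subject, day)
    }
    load_manual_mask(file.path(dir, row$path), ses$frames$WHITE)
  }
  nadh <- apply_mask(calibrate_frame(ses$frames$NADH, ses$refs$NADH), mask)
  fad <- apply_mask(calibrate_frame(ses$frames$FAD, ses$refs$FAD), mask)
  map <- redox_map(nadh, fad, mask, fad_floor = config$fad_floor)
  met <- surface_rr(map, subject = subject,
                    group = manifest$group[manifest$subject == subject][1],
                    day = day)
  hist <- rr_histogram(map, n_bins = config$hist_bins, range = config$hist_range)
  list(metrics = met, histogram = hist, map = map, mask = mask)
}

analyze_one_biopsy <- function(manifest, dir, subject, day, config) {
  stacks <- load_cryo(manifest, dir, subject, day)
  zn <- zero_background(flat_field_correct(stacks$nadh),
                        config$threshold_fraction)
  zf <- zero_background(flat_field_correct(stacks$fad),
                        config$threshold_fraction)
  mask <- cryo_wound_mask(zn$stack, zf$stack)
  map <- redox_map(zn$stack, zf$stack, mask, fad_floor = config$fad_floor)
  met <- volumetric_rr(map, subject = subject,
                       group = manifest$group[manifest$subject == subject][1],
                       day = day)
  list(metrics = met, map = map)
}

#' Analyze a cohort dataset (pipeline step)
#'
#' Runs the full processing chain on every in vivo session (load, cuvette
#' calibration, white-light segmentation, masking, redox map, Surface RR,
#' normalized area against the subject's day 0) and every biopsy (load,
#' flat-field correction, background zeroing, volumetric RR), then the
#' statistics layer (summary table, repeated-measures ANOVAs, Tukey post hoc
#' contrasts, Pearson correlations). A failure in one session is recorded
#' and does not stop the others.
#'
#' @param config A [run_config()] whose `dataset_dir` holds a cohort.
#' @return List (invisibly): `metrics` (per subject-day data frame),
#'   `summary`, `anova`, `correlations`, `failures`, `status` (0 = complete,
#'   2 = partial failures). Outputs are also written as CSV/JSON under
#'   `out_dir`.
#' @export
cmd_analyze <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$dataset_dir
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    rw_stop("rw_io_error", "no manifest at %s", manifest_path)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  sessions <- unique(manifest[manifest$kind == "tissue",
                              c("subject", "group", "day")])
  sessions <- sessions[order(sessions$subject, sessions$day), ]
  failures <- list()
  rows <- list()
  hists <- list()
  for (k in seq_len(nrow(sessions))) {
    s <- sessions$subject[k]; d <- sessions$day[k]
    res <- tryCatch(analyze_one_session(manifest, dir, s, d, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        subject = s, day = d, arm = "invivo", error = conditionMessage(res))
      next
    }
    m <- res$metrics
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, group = sessions$group[k], day = d,
      surface_rr = m$surface_rr, n_pixels = m$n_pixels, n_valid = m$n_valid)
    hists[[length(hists) + 1L]] <- data.frame(
      subject = s, group = sessions$group[k], day = d,
      bin = seq(0, config$hist_bins + 1),
      mid = c(NA, res$histogram$mids, NA),
      fraction = res$histogram$fraction)
    if (config$save_maps) {
      write_float_tiff(res$map$values,
                       file.path(config$out_dir,
                                 sprintf("%s_d%g_rr.tif", s, d)))
      write_frame_tiff(res$map$valid_mask * MAX_DN,
                       file.path(config$out_dir,
                                 sprintf("%s_d%g_rr_valid.tif", s, d)))
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(), group = character(), day = numeric(),
               surface_rr = numeric(), n_pixels = integer(),
               n_valid = integer())

  # normalized area against each subject's own day-0 count
  metrics$normalized_area <- NA_real_
  for (s in unique(metrics$subject)) {
    n0 <- metrics$n_pixels[metrics$subject == s & metrics$day == 0]
    if (length(n0) == 1) {
      idx <- metrics$subject == s
      metrics$normalized_area[idx] <- normalized_area(metrics$n_pixels[idx], n0)
    }
  }

  biopsies <- unique(manifest[manifest$kind == "stack",
                              c("subject", "group", "day")])
  vol_rows <- list()
  if (nrow(biopsies)) {
    biopsies <- biopsies[order(biopsies$subject, biopsies$day), ]
    for (k in seq_len(nrow(biopsies))) {
      s <- biopsies$subject[k]; d <- biopsies$day[k]
      res <- tryCatch(analyze_one_biopsy(manifest, dir, s, d, config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <- data.frame(
          subject = s, day = d, arm = "cryo", error = conditionMessage(res))
        next
      }
      vol_rows[[length(vol_rows) + 1L]] <- data.frame(
        subject = s, group = biopsies$group[k], day = d,
        volumetric_rr = res$metrics$volumetric_rr,
        n_voxels = res$metrics$n_voxels)
    }
  }
  volumetric <- if (length(vol_rows)) do.call(rbind, vol_rows) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else NULL

  # statistics layer
  full <- metrics
  full$volumetric_rr <- NA_real_
  if (!is.null(volumetric)) {
    key <- paste(volumetric$subject, volumetric$day)
    hit <- match(paste(full$subject, full$day), key)
    full$volumetric_rr <- volumetric$volumetric_rr[hit]
    extra <- volumetric[!key %in% paste(full$subject, full$day), ]
    if (nrow(extra)) {
      extra2 <- data.frame(subject = extra$subject, group = extra$group,
                           day = extra$day, surface_rr = NA_real_,
                           n_pixels = NA_integer_, n_valid = NA_integer_,
                           normalized_area = NA_real_,
                           volumetric_rr = extra$volumetric_rr)
      full <- rbind(full, extra2)
    }
  }

  summary_tab <- if (nrow(full)) summarize_cohort(full) else NULL
  anovas <- list()
  for (m in c("surface_rr", "normalized_area")) {
    res <- tryCatch(repeated_anova(metrics, m), error = function(e) e)
    anovas[[m]] <- if (inherits(res, "error")) {
      list(error = conditionMessage(res))
    } else {
      list(table = res$table, gg_epsilon = res$gg_epsilon)
    }
  }
  correlations <- list()
  ok <- is.finite(metrics$surface_rr) & is.finite(metrics$normalized_area)
  if (sum(ok) >= 3) {
    correlations$surface_vs_area <- tryCatch(
      pearson_fit(metrics$normalized_area[ok], metrics$surface_rr[ok]),
      error = function(e) list(error = conditionMessage(e)))
  }
  if (!is.null(volumetric)) {
    shared <- merge(metrics[c("subject", "day", "surface_rr")],
                    volumetric[c("subject", "day", "volumetric_rr")],
                    by = c("subject", "day"))
    if (nrow(shared) >= 3) {
      correlations$surface_vs_volumetric <- tryCatch(
        pearson_fit(shared$surface_rr, shared$volumetric_rr),
        error = function(e) list(error = conditionMessage(e)))
    }
  }

  utils::write.csv(full, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (length(hists)) {
    utils::write.csv(do.call(rbind, hists),
                     file.path(config$out_dir, "histograms.csv"),
                     row.names = FALSE)
  }
  if (!is.null(summary_tab)) {
    utils::write.csv(summary_tab, file.path(config$out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(anova = anovas, correlations = correlations,
         multiple_testing = "no adjustment across the three markers"),
    file.path(config$out_dir, "stats.json"),
    dataframe = "rows", digits = NA, auto_unbox = TRUE, na = "null")
  if (!is.null(failures)) {
    utils::write.csv(failures, file.path(config$out_dir, "failures.csv"),
                     row.names = FALSE)
  }
  write_resolved_config(config, config$out_dir)

  out <- list(metrics = full, summary = summary_tab, anova = anovas,
              correlations = correlations, failures = failures,
              status = if (is.null(failures)) 0L else 2L)
  invisible(out)
}

#' Render figures and a human-readable summary (pipeline step)
#'
#' From a completed analysis directory, writes one redox-histogram figure
#' per day (group-averaged bin fractions), a Surface RR vs normalized-area
#' scatter with its regression line, and a markdown summary table.
#'
#' @param config A [run_config()] whose `out_dir` holds analysis outputs.
#' @return Character vector of files written, invisibly.
#' @export
cmd_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  mpath <- file.path(config$out_dir, "metrics.csv")
  if (!file.exists(mpath)) {
    rw_stop("rw_io_error", "no metrics.csv under %s; run the analyze step first",
            config$out_dir)
  }
  metrics <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  if (!nrow(metrics)) rw_stop("rw_io_error", "metrics.csv is empty")
  written <- character()

  hpath <- file.path(config$out_dir, "histograms.csv")
  if (file.exists(hpath)) {
    hist <- utils::read.csv(hpath, stringsAsFactors = FALSE)
    hist <- hist[is.finite(hist$mid), ]
    for (d in sort(unique(hist$day))) {
      hd <- hist[hist$day == d, ]
      agg <- stats::aggregate(fraction ~ mid + group, hd, mean)
      p <- ggplot2::ggplot(agg, ggplot2::aes(x = mid, y = fraction,
                                             colour = group)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "redox ratio (NADH/FAD)", y = "fraction of wound pixels",
                      title = sprintf("Surface redox-ratio histogram, day %g", d)) +
        ggplot2::theme_minimal()
      f <- file.path(config$out_dir, sprintf("histogram_day%g.png", d))
      ggplot2::ggsave(f, p, width = 5, height = 3.5, dpi = 120)
      written <- c(written, f)
    }
  }

  ok <- is.finite(metrics$surface_rr) & is.finite(metrics$normalized_area)
  if (sum(ok) >= 3) {
    p <- ggplot2::ggplot(metrics[ok, ],
                         ggplot2::aes(x = normalized_area,
                                      y = surface_rr,
                                      colour = group)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                           formula = y ~ x, se = FALSE, colour = "black") +
      ggplot2::labs(x = "normalized wound area", y = "Surface RR") +
      ggplot2::theme_minimal()
    f <- file.path(config$out_dir, "surface_rr_vs_area.png")
    ggplot2::ggsave(f, p, width = 5, height = 3.5, dpi = 120)
    written <- c(written, f)
  }

  spath <- file.path(config$out_dir, "summary.csv")
  if (file.exists(spath)) {
    s <- utils::read.csv(spath, stringsAsFactors = FALSE)
    lines <- c("# Longitudinal wound assessment", "",
               "| marker | group | day | n | mean ± SE | significant |",
               "|---|---|---|---|---|---|")
    for (i in seq_len(nrow(s))) {
      se_txt <- if (is.finite(s$se[i])) sprintf("%.3f ± %.3f", s$mean[i], s$se[i])
                else sprintf("%.3f", s$mean[i])
      lines <- c(lines, sprintf("| %s | %s | %g | %d | %s | %s |",
                                s$marker[i], s$group[i], s$day[i], s$n[i],
                                se_txt,
                                ifelse(is.na(s$significant[i]), "-",
                                       ifelse(s$significant[i], "*", ""))))
    }
    f <- file.path(config$out_dir, "summary.md")
    writeLines(lines, f)
    written <- c(written, f)
  }
  invisible(written)
}
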