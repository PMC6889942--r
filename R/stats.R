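# Longitudinal statistics: two-factor repeated-measures (split-plot) ANOVA,
# Tukey HSD post hoc contrasts, Pearson correlation, percent differences and
# the cohort summary table. All quantities are computed from explicit sums
# of squares so the module is verifiable stand-alone; model-fitting
# functions are used only as cross-checks in the test suite.

validate_cohort_table <- function(table, response) {
  need <- c("subject", "group", "day", response)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    rw_stop("rw_design_error", "cohort table lacks columns: %s",
            paste(miss, collapse = ", "))
  }
  if (anyDuplicated(table[c("subject", "day")])) {
    rw_stop("rw_design_error", "(subject, day) rows must be unique")
  }
  if (length(unique(table$group)) < 1 || nrow(table) == 0) {
    rw_stop("rw_design_error", "cohort table is empty")
  }
  invisible(table)
}

#' Two-factor repeated-measures ANOVA
#'
#' Split-plot decomposition with group as the between-subject factor and day
#' as the within-subject (repeated) factor, computed from explicit sums of
#' squares: group, subject-within-group (between-subject error), day,
#' group x day, and day x subject-within-group (within-subject error).
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance of the repeated measures and reported alongside the
#' uncorrected p-values (which are the headline values); GG-adjusted
#' p-values are included for the within-subject effects.
#'
#' @param table Long-format cohort table with columns subject, group, day
#'   and the response.
#' @param response Name of the response column (e.g. `"surface_rr"`).
#' @return Object of class `rw_anova`: `table` (effect, ss, df, ms, f, p,
#'   p_gg), `gg_epsilon`, `grand_mean`, and `note` for degenerate inputs.
#' @export
repeated_anova <- function(table, response) {
  validate_cohort_table(table, response)
  days <- sort(unique(table$day))
  groups <- sort(unique(table$group))
  subjects <- unique(table[c("subject", "group")])
  # balance check: every subject at every day
  cells <- expand.grid(subject = subjects$subject, day = days,
                       stringsAsFactors = FALSE)
  key <- paste(table$subject, table$day)
  missing <- cells[!paste(cells$subject, cells$day) %in% key, ]
  if (nrow(missing)) {
    rw_stop("rw_design_error", "unbalanced design; missing cells: %s",
            paste(sprintf("%s@day%s", missing$subject, missing$day),
                  collapse = ", "))
  }
  n_g <- table(subjects$group)[groups]
  if (any(n_g < 2)) {
    rw_stop("rw_design_error", "need >= 2 subjects per group")
  }

  a <- length(groups); b <- length(days)
  # response matrix: subjects x days
  y <- matrix(NA_real_, nrow(subjects), b,
              dimnames = list(subjects$subject, days))
  for (i in seq_len(nrow(table))) {
    y[table$subject[i], as.character(table$day[i])] <- table[[response]][i]
  }
  grand <- mean(y)
  subj_means <- rowMeans(y)
  day_means <- colMeans(y)
  grp_of <- subjects$group
  grp_means <- vapply(groups, function(g) mean(y[grp_of == g, , drop = FALSE]),
                      numeric(1))

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- b * sum((subj_means - grand)^2)
  ss_group <- b * sum(n_g * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_day <- sum(n_g) * sum((day_means - grand)^2)
  cell_means <- vapply(groups, function(g) {
    colMeans(y[grp_of == g, , drop = FALSE])
  }, numeric(b))  # days x groups
  ss_gxd <- 0
  for (gi in seq_along(groups)) {
    ss_gxd <- ss_gxd + n_g[gi] * sum((cell_means[, gi] - grp_means[gi] -
                                        day_means + grand)^2)
  }
  ss_gxd <- unname(ss_gxd)
  ss_error <- ss_total - ss_between_subj - ss_day - ss_gxd

  df_group <- a - 1
  df_subj <- sum(n_g) - a
  df_day <- b - 1
  df_gxd <- (a - 1) * (b - 1)
  df_error <- df_subj * df_day

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_group <- ms(ss_group, df_group); ms_subj <- ms(ss_subj_within, df_subj)
  ms_day <- ms(ss_day, df_day); ms_gxd <- ms(ss_gxd, df_gxd)
  ms_error <- ms(ss_error, df_error)

  fstat <- function(ms_eff, ms_err) {
    if (!is.finite(ms_err) || ms_err <= 0) {
      if (is.finite(ms_eff) && ms_eff > 0) Inf else NA_real_
    } else ms_eff / ms_err
  }
  f_group <- fstat(ms_group, ms_subj)
  f_day <- fstat(ms_day, ms_error)
  f_gxd <- fstat(ms_gxd, ms_error)
  pval <- function(f, df1, df2) {
    if (!is.finite(f)) return(if (is.infinite(f)) 0 else NA_real_)
    stats::pf(f, df1, df2, lower.tail = FALSE)
  }

  # Greenhouse-Geisser epsilon from the pooled within-group covariance.
  S <- matrix(0, b, b)
  for (g in groups) {
    yg <- y[grp_of == g, , drop = FALSE]
    yc <- sweep(yg, 2, colMeans(yg))
    S <- S + crossprod(yc)
  }
  S <- S / (sum(n_g) - a)
  s_bar <- mean(S); d_bar <- mean(diag(S)); row_bar <- rowMeans(S)
  denom <- (b - 1) * (sum(S^2) - 2 * b * sum(row_bar^2) + b^2 * s_bar^2)
  gg_eps <- if (denom > 0) {
    min(1, b^2 * (d_bar - s_bar)^2 / denom)
  } else NA_real_
  p_gg <- function(f, df1, df2) {
    if (!is.finite(f) || !is.finite(gg_eps)) return(NA_real_)
    stats::pf(f, df1 * gg_eps, df2 * gg_eps, lower.tail = FALSE)
  }

  tab <- data.frame(
    effect = c("group", "subject_within_group", "day", "group_x_day",
               "day_x_subject_within_group"),
    ss = c(ss_group, ss_subj_within, ss_day, ss_gxd, ss_error),
    df = c(df_group, df_subj, df_day, df_gxd, df_error),
    ms = c(ms_group, ms_subj, ms_day, ms_gxd, ms_error),
    f = c(f_group, NA, f_day, f_gxd, NA),
    p = c(pval(f_group, df_group, df_subj), NA,
          pval(f_day, df_day, df_error), pval(f_gxd, df_gxd, df_error), NA),
    p_gg = c(NA, NA, p_gg(f_day, df_day, df_error),
             p_gg(f_gxd, df_gxd, df_error), NA)
  )
  note <- if (ss_total <= .Machine$double.eps * length(y)) {
    "no variance in the response; F statistics undefined"
  } else NA_character_
  structure(list(table = tab, gg_epsilon = unname(gg_eps),
                 grand_mean = grand, ss_total = ss_total,
                 response = response, note = note),
            class = "rw_anova")
}

#' @export
print.rw_anova <- function(x, ...) {
  cat(sprintf("Two-factor repeated-measures ANOVA on %s\n", x$response))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Greenhouse-Geisser epsilon: %.3f\n", x$gg_epsilon))
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Tukey HSD group contrasts per day
#'
#' At each day, all pairwise between-group contrasts with the studentized
#' range statistic `q = |mean diff| / sqrt(MSE * (1/n1 + 1/n2) / 2)` (the
#' Tukey-Kramer form; `sqrt(MSE/n)` for equal group sizes), where MSE is the
#' pooled within-group variance at that day. Adjusted p-values come from the
#' studentized range distribution.
#'
#' @param table Long-format cohort table.
#' @param response Response column name.
#' @param alpha Significance level for flags (default 0.05).
#' @return Data frame: day, group1, group2, mean_diff, q, p_adj, significant.
#' @export
tukey_posthoc <- function(table, response, alpha = 0.05) {
  validate_cohort_table(table, response)
  groups <- sort(unique(table$group))
  if (length(groups) < 2) {
    rw_stop("rw_contrast_error", "post hoc contrasts need >= 2 groups")
  }
  out <- list()
  for (day in sort(unique(table$day))) {
    td <- table[table$day == day, ]
    means <- tapply(td[[response]], td$group, mean)
    ns <- tapply(td[[response]], td$group, length)
    vars <- tapply(td[[response]], td$group, stats::var)
    df_err <- sum(ns - 1)
    mse <- sum((ns - 1) * vars) / df_err
    k <- length(groups)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        g1 <- groups[i]; g2 <- groups[j]
        diff <- unname(means[g1] - means[g2])
        se <- sqrt(mse / 2 * (1 / ns[g1] + 1 / ns[g2]))
        q <- if (se > 0) abs(diff) / se else if (abs(diff) > 0) Inf else 0
        p <- if (is.infinite(q)) 0 else
          stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          day = day, group1 = g1, group2 = g2, mean_diff = diff,
          q = unname(q), p_adj = unname(p), significant = unname(p < alpha)
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Pearson correlation and least-squares line
#'
#' Product-moment correlation from explicit sums, with the two-sided p-value
#' from the t transform and the least-squares slope and intercept.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List: `r`, `r_squared`, `p`, `slope`, `intercept`, `n`.
#' @export
pearson_fit <- function(x, y) {
  if (length(x) != length(y)) {
    rw_stop("rw_correlation_error", "x and y must have equal length")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rw_stop("rw_correlation_error", "need >= 3 paired observations")
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) {
    rw_stop("rw_correlation_error", "constant input: correlation undefined")
  }
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sxx * syy)
  r <- max(min(r, 1), -1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  slope <- sxy / sxx
  list(r = r, r_squared = r^2, p = p, slope = slope,
       intercept = mean(y) - slope * mean(x), n = n)
}

#' Percent difference relative to a reference mean
#'
#' `100 * (a - b) / a`: positive when the comparand `b` is lower than the
#' reference `a` (e.g. a 61% drop of the diabetic day-6 mean relative to
#' day 0).
#'
#' @param a Reference mean (nonzero).
#' @param b Comparand mean.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (a == 0) rw_stop("rw_metric_error", "reference mean must be nonzero")
  100 * (a - b) / a
}

#' Longitudinal cohort summary
#'
#' Mean and standard error (SD/sqrt(n)) per group, day and marker, with
#' significance flags from the per-day Tukey contrasts against the other
#' group. The three markers are not adjusted for multiple testing across
#' markers (noted in the output attributes).
#'
#' @param table Long-format cohort table.
#' @param markers Response columns to summarize (those present are used).
#' @param alpha Significance level.
#' @return Tidy data frame: marker, group, day, n, mean, se, significant.
#' @export
summarize_cohort <- function(table,
                             markers = c("surface_rr", "normalized_area",
                                         "volumetric_rr"),
                             alpha = 0.05) {
  markers <- intersect(markers, names(table))
  if (!length(markers)) rw_stop("rw_design_error", "no marker columns present")
  out <- list()
  for (m in markers) {
    tm <- table[is.finite(table[[m]]), ]
    if (!nrow(tm)) next
    flags <- NULL
    if (length(unique(tm$group)) >= 2 &&
        all(tapply(tm[[m]], list(tm$group, tm$day), length) >= 2, na.rm = TRUE)) {
      flags <- tukey_posthoc(tm, m, alpha = alpha)
    }
    for (g in sort(unique(tm$group))) {
      for (d in sort(unique(tm$day))) {
        v <- tm[[m]][tm$group == g & tm$day == d]
        if (!length(v)) next
        sig <- if (!is.null(flags)) {
          any(flags$significant[flags$day == d &
                                  (flags$group1 == g | flags$group2 == g)])
        } else NA
        out[[length(out) + 1L]] <- data.frame(
          marker = m, group = g, day = d, n = length(v), mean = mean(v),
          se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
          significant = sig
        )
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "multiple_testing") <-
    "per-day Tukey HSD within marker; no adjustment across markers"
  res
}
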