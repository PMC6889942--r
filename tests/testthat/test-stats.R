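# Repeated-measures ANOVA, Tukey post hoc contrasts, Pearson correlation,
# percent differences, cohort summary.

# independent brute-force split-plot decomposition used as the SS oracle
oracle_ss <- function(tab, resp) {
  subj <- unique(tab[c("subject", "group")])
  days <- sort(unique(tab$day))
  groups <- sort(unique(tab$group))
  y <- function(s, d) tab[[resp]][tab$subject == s & tab$day == d]
  grand <- mean(tab[[resp]])
  b <- length(days)
  ss_bs <- 0
  for (s in subj$subject) {
    ss_bs <- ss_bs + b * (mean(sapply(days, function(d) y(s, d))) - grand)^2
  }
  ss_group <- 0
  for (g in groups) {
    n_g <- sum(subj$group == g)
    gm <- mean(tab[[resp]][tab$group == g])
    ss_group <- ss_group + n_g * b * (gm - grand)^2
  }
  ss_day <- 0
  for (d in days) ss_day <- ss_day + nrow(subj) * (mean(tab[[resp]][tab$day == d]) - grand)^2
  ss_gxd <- 0
  for (g in groups) for (d in days) {
    n_g <- sum(subj$group == g)
    cm <- mean(tab[[resp]][tab$group == g & tab$day == d])
    gm <- mean(tab[[resp]][tab$group == g])
    dm <- mean(tab[[resp]][tab$day == d])
    ss_gxd <- ss_gxd + n_g * (cm - gm - dm + grand)^2
  }
  ss_total <- sum((tab[[resp]] - grand)^2)
  list(group = ss_group, subj_within = ss_bs - ss_group, day = ss_day,
       gxd = ss_gxd, error = ss_total - ss_bs - ss_day - ss_gxd,
       total = ss_total)
}

rand_table <- function(n = 3, days = c(0, 2, 4), sd = 1, group_shift = 0) {
  subj <- c(sprintf("c%d", 1:n), sprintf("d%d", 1:n))
  grp <- rep(c("control", "diabetic"), each = n)
  tab <- expand.grid(subject = subj, day = days, stringsAsFactors = FALSE)
  tab$group <- grp[match(tab$subject, subj)]
  tab$y <- rnorm(nrow(tab), sd = sd) +
    ifelse(tab$group == "diabetic", group_shift * tab$day, 0)
  tab
}

test_that("the split-plot decomposition matches the brute-force oracle and aov", {
  set.seed(31)
  for (rep in 1:3) {
    tab <- rand_table(n = 3 + rep)
    fit <- repeated_anova(tab, "y")
    orc <- oracle_ss(tab, "y")
    ss <- setNames(fit$table$ss, fit$table$effect)
    expect_equal(unname(ss["group"]), orc$group, tolerance = 1e-9)
    expect_equal(unname(ss["subject_within_group"]), orc$subj_within, tolerance = 1e-9)
    expect_equal(unname(ss["day"]), orc$day, tolerance = 1e-9)
    expect_equal(unname(ss["group_x_day"]), orc$gxd, tolerance = 1e-9)
    expect_equal(unname(ss["day_x_subject_within_group"]), orc$error, tolerance = 1e-9)
    # decomposition identity
    expect_equal(sum(fit$table$ss), fit$ss_total,
                 tolerance = 1e-9 * max(1, fit$ss_total))

    # cross-check against the standard split-plot fit
    tab$dayf <- factor(tab$day)
    av <- summary(stats::aov(y ~ group * dayf + Error(subject / dayf), data = tab))
    between <- av[["Error: subject"]][[1]]
    within <- av[["Error: subject:dayf"]][[1]]
    expect_equal(unname(ss["group"]), between["group", "Sum Sq"], tolerance = 1e-8)
    expect_equal(unname(ss["subject_within_group"]),
                 between["Residuals", "Sum Sq"], tolerance = 1e-8)
    expect_equal(unname(ss["day"]), within["dayf", "Sum Sq"], tolerance = 1e-8)
    expect_equal(unname(ss["group_x_day"]), within["group:dayf", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(unname(ss["day_x_subject_within_group"]),
                 within["Residuals", "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("a planted pure group effect has closed-form SS and zero error", {
  days <- c(0, 2)
  tab <- expand.grid(subject = c("a", "b", "c", "d"), day = days,
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$subject %in% c("a", "b"), "control", "diabetic")
  tab$y <- ifelse(tab$group == "control", 1, 3)  # no noise
  fit <- repeated_anova(tab, "y")
  ss <- setNames(fit$table$ss, fit$table$effect)
  grand <- 2
  expect_equal(unname(ss["group"]),
               length(days) * (2 * (1 - grand)^2 + 2 * (3 - grand)^2))
  expect_equal(unname(ss["subject_within_group"]), 0)
  expect_equal(unname(ss["day_x_subject_within_group"]), 0)
})

test_that("constant responses are reported as the no-variance case", {
  tab <- rand_table(n = 2, days = c(0, 2))
  tab$y <- 5
  fit <- repeated_anova(tab, "y")
  expect_false(is.na(fit$note))
  expect_true(all(fit$table$ss < 1e-20))
})

test_that("unbalanced tables raise a design error listing missing cells", {
  tab <- rand_table(n = 3)
  tab <- tab[!(tab$subject == "c1" & tab$day == 2), ]
  expect_error(repeated_anova(tab, "y"), regexp = "c1@day2",
               class = "rw_design_error")
})

test_that("Tukey contrasts follow the studentized-range formula", {
  # identical groups: zero difference, p ~ 1
  tab <- rand_table(n = 4, days = 0)
  tab$y <- rep(rep(c(1, 2, 3, 4), 2), 1)
  res <- tukey_posthoc(tab, "y")
  expect_equal(res$mean_diff, 0)
  expect_gt(res$p_adj, 0.99)

  # 10-pooled-SD separation with n = 6 is significant
  set.seed(17)
  tab2 <- rand_table(n = 6, days = 0, sd = 1)
  tab2$y <- tab2$y + ifelse(tab2$group == "diabetic", 10, 0)
  res2 <- tukey_posthoc(tab2, "y")
  expect_true(res2$significant)
  expect_lt(res2$p_adj, 0.05)

  # q equals mean-diff / sqrt(MSE/n) by direct computation
  set.seed(23)
  tab3 <- rand_table(n = 5, days = 0)
  res3 <- tukey_posthoc(tab3, "y")
  v <- tapply(tab3$y, tab3$group, var)
  mse <- mean(v)  # equal n: pooled = mean of variances
  md <- unname(diff(rev(tapply(tab3$y, tab3$group, mean))))
  expect_equal(res3$q, abs(md) / sqrt(mse / 5), tolerance = 1e-12)
  expect_equal(res3$p_adj,
               ptukey(res3$q, 2, 8, lower.tail = FALSE), tolerance = 1e-12)

  expect_error(tukey_posthoc(tab3[tab3$group == "control", ], "y"),
               class = "rw_contrast_error")
})

test_that("Pearson correlation matches the explicit formula and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_fit(x, -2 * x + 3)$r, -1)
  expect_equal(pearson_fit(x, -2 * x + 3)$r_squared, 1)
  expect_equal(pearson_fit(x, -2 * x + 3)$slope, -2)
  expect_equal(pearson_fit(x, -2 * x + 3)$intercept, 3)

  # 5-point toy fixture against the covariance/(sd*sd) loop
  y <- c(2.1, 1.4, 3.3, 0.2, 2.8)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in 1:5) {
    sxy <- sxy + (x[i] - mean(x)) * (y[i] - mean(y))
    sxx <- sxx + (x[i] - mean(x))^2
    syy <- syy + (y[i] - mean(y))^2
  }
  fit <- pearson_fit(x, y)
  expect_equal(fit$r, sxy / sqrt(sxx * syy), tolerance = 1e-12)
  ct <- cor.test(x, y)
  expect_equal(fit$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(fit$p, ct$p.value, tolerance = 1e-10)
  # symmetry and affine invariance of r^2
  expect_equal(pearson_fit(y, x)$r, fit$r, tolerance = 1e-12)
  expect_equal(pearson_fit(3 * x + 1, y)$r_squared, fit$r_squared,
               tolerance = 1e-12)

  # large-n independent vectors decorrelate
  set.seed(8)
  expect_lt(abs(pearson_fit(rnorm(2000), rnorm(2000))$r), 0.08)
  expect_error(pearson_fit(rep(1, 5), y), class = "rw_correlation_error")
  expect_error(pearson_fit(1:2, 1:2), class = "rw_correlation_error")
})

test_that("percent difference uses the reference-relative drop convention", {
  expect_equal(percent_difference(1.5, 1.5), 0)
  expect_equal(percent_difference(1.2, 0.468), 61.0)
  expect_equal(percent_difference(1.2, 0.408), 66.0)
  expect_error(percent_difference(0, 1), class = "rw_metric_error")
})

test_that("the cohort summary reports mean, SE and per-day significance", {
  tab <- data.frame(subject = c("a", "b", "c", "d", "e", "f"),
                    group = rep(c("control", "diabetic"), each = 3),
                    day = 0,
                    surface_rr = c(1, 2, 3, 1.1, 2.1, 3.1))
  s <- summarize_cohort(tab, markers = "surface_rr")
  ctrl <- s[s$group == "control", ]
  expect_equal(ctrl$mean, 2)
  expect_equal(ctrl$se, sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-9)
  expect_equal(ctrl$se, 0.5774, tolerance = 1e-4)

  # single subject per cell: SE absent
  one <- data.frame(subject = c("a", "b"), group = c("control", "diabetic"),
                    day = 0, surface_rr = c(1, 2))
  s1 <- summarize_cohort(one, markers = "surface_rr")
  expect_true(all(is.na(s1$se)))

  # planted default cohort: diabetic flagged from day 2 on, not at day 0
  p <- cohort_params(seed = 1)
  truth <- cohort_truth(p)$surface
  truth$surface_rr <- truth$rr_true
  s2 <- summarize_cohort(truth, markers = "surface_rr")
  diab <- s2[s2$group == "diabetic", ]
  expect_false(diab$significant[diab$day == 0])
  expect_true(all(diab$significant[diab$day %in% c(2, 4, 6)]))
})
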