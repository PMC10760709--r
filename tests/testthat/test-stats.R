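test_that("subject-condition means derive speeds from timed durations", {
  subjects <- data.frame(subject_id = 1, age_yr = 40, mass_kg = 65,
                         height_m = 1.7, leg_length_pros_m = 1,
                         leg_length_intact_m = 1, level = "BK",
                         affected_side = "R", sex = "M", hours_on_legs = 5,
                         years_since_amputation = 10)
  trials <- data.frame(
    subject_id = 1,
    task = c(rep("straight", 4), "circle"),
    distance_m = c(rep(10, 4), NA),
    radius_m = c(rep(NA, 4), 1),
    laps = c(rep(NA, 4), 5),
    direction = c(rep(NA, 4), "prosthesis_in"),
    trial_index = c(1:4, 1),
    duration_s = c(9, 10, 10, 11, 10 * pi))
  m <- subject_condition_means(new_cohort(subjects, trials))
  straight <- m[m$task == "straight", ]
  expect_equal(straight$mean_speed, mean(c(10 / 9, 1, 1, 10 / 11)))
  expect_equal(straight$n_trials, 4L)
  circ <- m[m$task == "circle" & m$direction == "pooled", ]
  expect_equal(circ$mean_speed, 5 * 2 * pi * 1 / (10 * pi))  # exactly 1 m/s
  trials$duration_s[2] <- -1
  expect_error(subject_condition_means(new_cohort(subjects, trials)),
               "positive")
})

test_that("percent reduction is relative to the 23 m bout and scale-free", {
  flat <- tiny_cohort(function(i, task, cond, dir) 1.2, n_subjects = 4)
  pr <- percent_reduction(flat)
  expect_true(all(abs(pr$mean_pct) < 1e-12))
  expect_true(all(pr$sd_pct < 1e-12))
  # every non-baseline condition at 90% of the 23 m speed: 10 +/- 0 %
  v90 <- function(i, task, cond, dir)
    if (task == "straight" && cond == 23) 1.5 else 0.9 * 1.5
  pr90 <- percent_reduction(tiny_cohort(v90, n_subjects = 4))
  expect_equal(pr90$mean_pct, rep(10, nrow(pr90)), tolerance = 1e-10)
  # rescaling every speed leaves the percentages unchanged
  v_var <- function(i, task, cond, dir) 1 + 0.05 * i + 0.02 * cond
  pr1 <- percent_reduction(tiny_cohort(v_var, n_subjects = 4))
  pr2 <- percent_reduction(tiny_cohort(function(i, task, cond, dir)
    3.3 * v_var(i, task, cond, dir), n_subjects = 4))
  expect_equal(pr1$mean_pct, pr2$mean_pct, tolerance = 1e-10)
  expect_equal(pr1$sd_pct, pr2$sd_pct, tolerance = 1e-10)
  # the per-group split covers all three pools
  expect_setequal(unique(pr1$group), c("all", "above_knee", "below_knee"))
})

test_that("paired bootstrap p behaves at the deterministic extremes", {
  x <- rep(1, 12)
  up <- bootstrap_paired_onesided(x, x + 0.2, n_boot = 5000, seed = 2)
  expect_true(up$floored)
  expect_equal(up$p_raw, 1 / 5000)
  expect_equal(up$p_bonferroni, 10 / 5000)
  same <- bootstrap_paired_onesided(x, x, n_boot = 2000, seed = 2)
  expect_equal(same$p_raw, 1)
  expect_equal(same$p_bonferroni, 1)
  expect_error(bootstrap_paired_onesided(1, 2), "2 subjects")
})

test_that("bootstrap p is reproducible, shift-invariant and monotone in the effect", {
  set.seed(31)
  x <- rnorm(12); y <- x + rnorm(12, 0.1, 0.3)
  a <- bootstrap_paired_onesided(x, y, n_boot = 20000, seed = 77)
  b <- bootstrap_paired_onesided(x, y, n_boot = 20000, seed = 77)
  expect_identical(a$p_raw, b$p_raw)          # fixed seed, bit-identical
  shift <- bootstrap_paired_onesided(x + 5, y + 5, n_boot = 20000, seed = 77)
  expect_identical(shift$p_raw, a$p_raw)      # differences unchanged
  perm <- sample(12)
  reord <- bootstrap_paired_onesided(x[perm], y[perm], n_boot = 20000,
                                     seed = 77)
  expect_lt(abs(reord$p_raw - a$p_raw), 0.02) # ordering: same estimand
  # adding delta to y can only shrink p (same resamples)
  p_prev <- a$p_raw
  for (delta in c(0.05, 0.2, 0.5)) {
    p_new <- bootstrap_paired_onesided(x, y + delta, n_boot = 20000,
                                       seed = 77)$p_raw
    expect_lte(p_new, p_prev)
    p_prev <- p_new
  }
  # the caller's RNG stream is not consumed
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  invisible(bootstrap_paired_onesided(x, y, n_boot = 100, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("paired one-sided t-test matches the t distribution and flags degeneracy", {
  d3 <- c(0.1, 0.2, 0.3)
  res <- paired_t_onesided(rep(0, 3), d3)
  expect_equal(res$t, 0.2 / (sd(d3) / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p_raw, pt(0.2 / (sd(d3) / sqrt(3)), df = 2,
                             lower.tail = FALSE), tolerance = 1e-12)
  sym <- paired_t_onesided(c(0, 0), c(-1, 1))
  expect_equal(sym$p_raw, 0.5)
  deg <- paired_t_onesided(rep(0, 4), rep(1, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$p_raw, 0)
  deg0 <- paired_t_onesided(rep(2, 4), rep(2, 4))
  expect_true(deg0$degenerate)
  expect_equal(deg0$p_raw, 1)
})

test_that("bootstrap p is approximately uniform under the paired null", {
  set.seed(88)
  reps <- 2000
  n <- 12
  n_boot <- 400
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- rnorm(n)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    pvals[r] <- mean(colMeans(matrix(d[idx], nrow = n)) <= 0)
  }
  ks <- max(abs(sort(pvals) - (seq_len(reps) - 0.5) / reps))
  expect_lt(ks, 0.1)
})

test_that("fixed-effects linear fit recovers exact slopes and matches normal equations", {
  dat <- expand.grid(subject_id = 1:4, predictor = c(4, 6, 8, 10))
  dat$speed <- 0.02 * dat$predictor + c(1.0, 1.1, 1.2, 1.3)[dat$subject_id]
  fit <- linear_fit_subject_offsets(dat)
  expect_equal(fit$slope, 0.02, tolerance = 1e-12)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$subject_offsets), c(1.0, 1.1, 1.2, 1.3),
               tolerance = 1e-12)
  set.seed(19)
  dat$speed <- dat$speed + rnorm(nrow(dat), 0, 0.05)
  fit2 <- linear_fit_subject_offsets(dat)
  X <- cbind(sapply(1:4, function(i) as.numeric(dat$subject_id == i)),
             dat$predictor)
  beta <- solve(crossprod(X), crossprod(X, dat$speed))
  expect_equal(fit2$slope, beta[5], tolerance = 1e-10)
  expect_equal(unname(fit2$subject_offsets), beta[1:4], tolerance = 1e-10)
  expect_error(linear_fit_subject_offsets(
    data.frame(subject_id = 1:3, predictor = 2, speed = 1)), "distinct")
})

test_that("a cohort with identical speeds everywhere yields no significant tests", {
  flat <- tiny_cohort(function(i, task, cond, dir) 1.1, n_subjects = 4)
  bat <- run_hypothesis_battery(flat, n_boot = 1000, seed = 4)
  for (r in bat) {
    expect_false(isTRUE(r$skipped))
    if (!isTRUE(r$post_hoc)) expect_equal(r$p_bonferroni, 1)
    expect_equal(r$statistic, 0, tolerance = 1e-12)
  }
})

test_that("the battery detects distance and radius effects but not an absent direction effect", {
  strong <- list(
    above_knee = modify_coefficients(steady_coefficients("above_knee"),
                                     list(a_change = 4, a_turn = 15)),
    below_knee = modify_coefficients(steady_coefficients("below_knee"),
                                     list(a_change = 4, a_turn = 15)))
  co <- generate_cohort(synthetic_config(coeffs = strong,
                                         sigma_subject = 0.06,
                                         sigma_trial = 0.03,
                                         direction_effect = 0, seed = 42))
  bat <- run_hypothesis_battery(co, n_boot = 2000, seed = 42)
  names(bat) <- vapply(bat, `[[`, character(1), "name")
  for (nm in c("straight_4m_slower_than_23m", "straight_6m_slower_than_23m",
               "straight_8m_slower_than_23m", "straight_10m_slower_than_23m",
               "circle_1m_slower_than_23m", "circle_2m_slower_than_23m",
               "circle_3m_slower_than_23m", "distance_slope_positive",
               "radius_slope_positive"))
    expect_lt(bat[[nm]]$p_bonferroni, 0.05)
  expect_gt(bat[["prosthesis_out_faster_than_in"]]$p_bonferroni, 0.05)
  expect_true(bat[["prosthesis_out_faster_than_in_AK_only"]]$post_hoc)
  expect_true(is.na(bat[["prosthesis_out_faster_than_in_AK_only"]]$p_bonferroni))
  # a battery re-run with the same seed is bit-identical
  bat2 <- run_hypothesis_battery(co, n_boot = 2000, seed = 42)
  expect_identical(lapply(unname(bat), unclass), lapply(bat2, unclass))
})

test_that("a missing condition is reported as a skipped test, not an error", {
  co <- tiny_cohort(function(i, task, cond, dir) 1 + 0.01 * cond)
  tr <- cohort_trials(co)
  tr <- tr[!(tr$task == "circle" & tr$radius_m == 2), ]
  co2 <- new_cohort(cohort_subjects(co), tr)
  bat <- run_hypothesis_battery(co2, n_boot = 500, seed = 1)
  names(bat) <- vapply(bat, `[[`, character(1), "name")
  expect_true(isTRUE(bat[["circle_2m_slower_than_23m"]]$skipped))
  expect_false(isTRUE(bat[["circle_1m_slower_than_23m"]]$skipped))
})
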