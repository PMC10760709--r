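# shared fixtures and independent oracles, built in code

noiseless_cohort <- function(seed = 11, ...) {
  generate_cohort(synthetic_config(sigma_subject = 0, sigma_trial = 0,
                                   seed = seed, ...))
}

group_trials <- function(cohort, level) {
  ids <- cohort_subjects(cohort)$subject_id[
    cohort_subjects(cohort)$level == level]
  tr <- cohort_trials(cohort)
  tr[tr$subject_id %in% ids, ]
}

# minimal hand-built cohort: one speed per (subject, condition), durations
# back-computed so the loader re-derives exactly these speeds
tiny_cohort <- function(speed_fn, n_subjects = 3,
                        levels = rep(c("AK", "BK"), length.out = n_subjects),
                        distances = c(4, 6, 8, 10, 23),
                        radii = c(1, 2, 3), laps = c(5, 4, 3),
                        n_straight_trials = 1) {
  subjects <- data.frame(
    subject_id = seq_len(n_subjects), age_yr = 40, mass_kg = 65,
    height_m = 1.67, leg_length_pros_m = 1, leg_length_intact_m = 1,
    level = levels, affected_side = "R", sex = "M", hours_on_legs = 5,
    years_since_amputation = 10, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    for (d in distances) for (tr in seq_len(n_straight_trials)) {
      v <- speed_fn(i, "straight", d, NA)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = i, task = "straight", distance_m = d,
        radius_m = NA_real_, laps = NA_integer_, direction = NA_character_,
        trial_index = tr, duration_s = d / v, stringsAsFactors = FALSE)
    }
    for (ri in seq_along(radii)) {
      for (dir in c("prosthesis_in", "prosthesis_out")) {
        v <- speed_fn(i, "circle", radii[ri], dir)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = i, task = "circle", distance_m = NA_real_,
          radius_m = radii[ri], laps = laps[ri], direction = dir,
          trial_index = 1L,
          duration_s = laps[ri] * 2 * pi * radii[ri] / v,
          stringsAsFactors = FALSE)
      }
    }
  }
  new_cohort(subjects, do.call(rbind, rows))
}

# brute-force oracles: dense-grid minimisers of the cost curves
grid_opt_straight <- function(coeffs, D, eff = efficiency_params(),
                              step = 1e-5) {
  v_max <- sqrt(coeffs$a0 / coeffs$a2)
  v <- seq(step, v_max - step, by = step)
  v[which.min(bout_total_cost(coeffs, D, v, eff))]
}

grid_opt_circle <- function(coeffs, R, step = 1e-5) {
  v_max <- sqrt(coeffs$a0 / coeffs$a2)
  v <- seq(step, v_max - step / 2, by = step)
  v[which.min(circle_cost_per_distance(coeffs, v, R))]
}
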