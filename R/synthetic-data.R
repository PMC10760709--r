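#' Configuration for the synthetic cohort generator
#'
#' Encodes the study's trial design and the generative model for speeds.
#' Defaults reproduce the protocol: 7 above-knee and 5 below-knee subjects;
#' straight bouts of 4, 6, 8, 10 and 23 m with four trials each; circles of
#' radius 1, 2 and 3 m walked for 5, 4 and 3 laps, once per turning
#' direction — 26 trials per subject. Group coefficients default to the
#' literature steady-rate values merged with the published changing-speed
#' and turning estimates ([reference_coefficients()], version 1).
#'
#' Each subject's speed in condition `c` is
#' `v_opt(c) * exp(b_i) * exp(e_ict)` with subject factor
#' `b_i ~ N(0, sigma_subject^2)` and trial noise `e ~ N(0, sigma_trial^2)`,
#' plus `direction_effect` (m/s) on prosthesis-out circle trials. The
#' default sigmas (0.08, 0.04) give across-subject coefficients of
#' variation of the order seen in cohort speed summaries; multiplicative
#' (lognormal) noise keeps speeds and durations positive.
#'
#' @param n_above_knee,n_below_knee Subjects per amputation group.
#' @param coeffs Named list of `walk_coeffs` per group
#'   (`above_knee`, `below_knee`).
#' @param sigma_subject S.d. of the log subject factor (default 0.08).
#' @param sigma_trial S.d. of the log trial noise (default 0.04).
#' @param direction_effect Additive speed bonus, m/s, for prosthesis-out
#'   circle trials (default 0).
#' @param distances Straight bout distances, m.
#' @param n_straight_trials Trials per distance.
#' @param radii Circle radii, m.
#' @param laps Laps walked at each radius.
#' @param eff [efficiency_params()].
#' @param seed Single RNG seed for the whole cohort.
#' @return An object of class `walk_synth_config`.
#' @export
synthetic_config <- function(n_above_knee = 7, n_below_knee = 5,
                             coeffs = list(
                               above_knee = reference_coefficients("above_knee"),
                               below_knee = reference_coefficients("below_knee")),
                             sigma_subject = 0.08, sigma_trial = 0.04,
                             direction_effect = 0,
                             distances = c(4, 6, 8, 10, 23),
                             n_straight_trials = 4,
                             radii = c(1, 2, 3), laps = c(5, 4, 3),
                             eff = efficiency_params(), seed = 1) {
  stopifnot(sigma_subject >= 0, sigma_trial >= 0,
            length(radii) == length(laps),
            n_above_knee + n_below_knee >= 1)
  for (g in names(coeffs)) stopifnot(inherits(coeffs[[g]], "walk_coeffs"))
  structure(list(n_above_knee = n_above_knee, n_below_knee = n_below_knee,
                 coeffs = coeffs, sigma_subject = sigma_subject,
                 sigma_trial = sigma_trial,
                 direction_effect = direction_effect,
                 distances = distances,
                 n_straight_trials = n_straight_trials,
                 radii = radii, laps = laps, eff = eff, seed = seed),
            class = "walk_synth_config")
}

# covariate ranges span the published subject table; schema fidelity only —
# covariates never influence generated speeds
sample_subjects <- function(n_ak, n_bk) {
  n <- n_ak + n_bk
  data.frame(
    subject_id = seq_len(n),
    age_yr = round(stats::runif(n, 21, 60)),
    mass_kg = round(stats::runif(n, 47, 90)),
    height_m = round(stats::runif(n, 1.54, 1.84), 2),
    leg_length_pros_m = round(stats::runif(n, 0.86, 1.07), 2),
    leg_length_intact_m = round(stats::runif(n, 0.86, 1.05), 2),
    level = c(rep("AK", n_ak), rep("BK", n_bk)),
    affected_side = sample(c("L", "R"), n, replace = TRUE, prob = c(0.75, 0.25)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(11 / 12, 1 / 12)),
    hours_on_legs = round(stats::runif(n, 1, 10)),
    years_since_amputation = round(stats::runif(n, 2, 30)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort under the study design
#'
#' Draws subjects and timed trials according to a [synthetic_config()]:
#' condition speeds are the group's model-optimal speeds perturbed by
#' lognormal subject and trial factors, and trial durations are
#' back-computed (`T = D/v` for straight bouts,
#' `T = laps * 2*pi*R / v` for circles) so that re-deriving speeds from the
#' emitted durations reproduces the generated speeds.
#'
#' @param config A [synthetic_config()].
#' @return A `walk_cohort` with synthetic provenance.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "walk_synth_config"))
  with_preserved_seed(config$seed, {
    subjects <- sample_subjects(config$n_above_knee, config$n_below_knee)
    rows <- list()
    for (i in seq_len(nrow(subjects))) {
      grp <- group_from_level(subjects$level[i])
      cf <- config$coeffs[[grp]]
      if (is.null(cf)) stop("no coefficients supplied for group ", grp,
                            call. = FALSE)
      b_i <- stats::rnorm(1, 0, config$sigma_subject)
      v_straight <- optimal_speed_straight(cf, config$distances, config$eff)
      for (di in seq_along(config$distances)) {
        for (tr in seq_len(config$n_straight_trials)) {
          v <- v_straight[di] * exp(b_i) *
            exp(stats::rnorm(1, 0, config$sigma_trial))
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subjects$subject_id[i], task = "straight",
            distance_m = config$distances[di], radius_m = NA_real_,
            laps = NA_integer_, direction = NA_character_,
            trial_index = tr, duration_s = config$distances[di] / v,
            speed = v, stringsAsFactors = FALSE)
        }
      }
      v_circle <- optimal_speed_circle(cf, config$radii)
      for (ri in seq_along(config$radii)) {
        for (dir in c("prosthesis_in", "prosthesis_out")) {
          v <- v_circle[ri] * exp(b_i) *
            exp(stats::rnorm(1, 0, config$sigma_trial)) +
            if (dir == "prosthesis_out") config$direction_effect else 0
          if (v <= 0)
            stop("generated non-positive speed (direction_effect too negative)",
                 call. = FALSE)
          path <- config$laps[ri] * 2 * pi * config$radii[ri]
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = subjects$subject_id[i], task = "circle",
            distance_m = NA_real_, radius_m = config$radii[ri],
            laps = config$laps[ri], direction = dir,
            trial_index = 1L, duration_s = path / v,
            speed = v, stringsAsFactors = FALSE)
        }
      }
    }
    new_cohort(subjects, do.call(rbind, rows),
               provenance = list(type = "synthetic", config = config))
  })
}

#' Write the canonical fixture cohorts
#'
#' Emits three cohorts as CSV pairs plus a JSON sidecar with the generating
#' configuration: `noiseless` (zero subject and trial noise, so every trial
#' speed equals the group's model-optimal speed), `noisy`
#' (sigma_subject = 0.08, sigma_trial = 0.04, seed 20240102) and `null`
#' (changing-speed and turning coefficients set to zero, so speeds carry no
#' distance or radius dependence — a calibration fixture for the test
#' battery).
#'
#' @param out_dir Writable directory.
#' @return Named list of the file paths written, invisibly.
#' @export
make_fixture_suite <- function(out_dir) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  null_coeffs <- list(
    above_knee = modify_coefficients(steady_coefficients("above_knee"),
                                     list(a_change = 0, a_turn = 0)),
    below_knee = modify_coefficients(steady_coefficients("below_knee"),
                                     list(a_change = 0, a_turn = 0)))
  configs <- list(
    noiseless = synthetic_config(sigma_subject = 0, sigma_trial = 0,
                                 seed = 20240101),
    noisy = synthetic_config(sigma_subject = 0.08, sigma_trial = 0.04,
                             seed = 20240102),
    null = synthetic_config(coeffs = null_coeffs, sigma_subject = 0.08,
                            sigma_trial = 0.04, seed = 20240103))
  paths <- list()
  for (nm in names(configs)) {
    cohort <- generate_cohort(configs[[nm]])
    paths[[nm]] <- write_cohort(cohort, out_dir, prefix = nm)
  }
  invisible(paths)
}
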