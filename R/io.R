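#' Construct a cohort dataset
#'
#' A cohort bundles a subject table and a trial table and is the common
#' currency of the analysis functions. Trials must reference existing
#' subjects and be unique in (subject, task, condition, direction,
#' trial index); straight trials need a distance, circle trials a radius
#' and lap count; durations must be positive. Trial speeds are derived
#' from the durations (`D/T`; `laps * 2*pi*R / T`).
#'
#' @param subjects Data frame with columns `subject_id`, `age_yr`,
#'   `mass_kg`, `height_m`, `leg_length_pros_m`, `leg_length_intact_m`,
#'   `level` (`"BK"`/`"AK"`), `affected_side`, `sex`, `hours_on_legs`,
#'   `years_since_amputation`.
#' @param trials Data frame with columns `subject_id`, `task`,
#'   `distance_m`, `radius_m`, `laps`, `direction`, `trial_index`,
#'   `duration_s` (and optionally a pre-derived `speed`, which is
#'   recomputed).
#' @param provenance List describing the data origin
#'   (`type = "real"`/`"synthetic"` plus source path or config).
#' @return An object of class `walk_cohort`.
#' @export
new_cohort <- function(subjects, trials,
                       provenance = list(type = "real", source = NA)) {
  stopifnot(is.data.frame(subjects), is.data.frame(trials))
  req_s <- c("subject_id", "level")
  miss <- setdiff(req_s, names(subjects))
  if (length(miss)) stop("subject table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_level <- setdiff(unique(subjects$level), c("BK", "AK"))
  if (length(bad_level))
    stop("unknown amputation level code(s): ",
         paste(bad_level, collapse = ", "), " (expected BK or AK)",
         call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in subject table", call. = FALSE)
  req_t <- c("subject_id", "task", "distance_m", "radius_m", "laps",
             "direction", "trial_index", "duration_s")
  miss <- setdiff(req_t, names(trials))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  orphan <- setdiff(unique(trials$subject_id), subjects$subject_id)
  if (length(orphan))
    stop("trial(s) reference unknown subject id(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  if (!is.numeric(trials$duration_s) || any(!is.finite(trials$duration_s)) ||
      any(trials$duration_s <= 0))
    stop("all trial durations must be positive numbers; offending row(s): ",
         paste(utils::head(which(!is.finite(trials$duration_s) |
                                   trials$duration_s <= 0), 5),
               collapse = ", "), call. = FALSE)
  check_trials(trials)
  key <- with(trials, paste(subject_id, task,
                            ifelse(task == "straight", distance_m, radius_m),
                            ifelse(task == "straight", "", direction),
                            trial_index))
  if (anyDuplicated(key))
    stop("duplicate trial key(s) at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "),
         call. = FALSE)
  trials$speed <- ifelse(trials$task == "straight",
                         trials$distance_m / trials$duration_s,
                         trials$laps * 2 * pi * trials$radius_m /
                           trials$duration_s)
  structure(list(subjects = subjects, trials = trials,
                 provenance = provenance), class = "walk_cohort")
}

#' @export
print.walk_cohort <- function(x, ...) {
  cat(sprintf("Walking cohort (%s): %d subjects (%d AK, %d BK), %d trials (%d straight, %d circle)\n",
              x$provenance$type, nrow(x$subjects),
              sum(x$subjects$level == "AK"), sum(x$subjects$level == "BK"),
              nrow(x$trials), sum(x$trials$task == "straight"),
              sum(x$trials$task == "circle")))
  invisible(x)
}

#' @rdname new_cohort
#' @param cohort A `walk_cohort`.
#' @export
cohort_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "walk_cohort"))
  cohort$subjects
}

#' @rdname new_cohort
#' @export
cohort_trials <- function(cohort) {
  stopifnot(inherits(cohort, "walk_cohort"))
  cohort$trials
}

#' Read a cohort from its two-CSV representation
#'
#' Loads the subject and trial tables, optionally renaming columns from a
#' user-supplied mapping (for ingesting externally deposited files whose
#' headers differ), validates the schema and derives trial speeds.
#'
#' @param subjects_path,trials_path CSV file paths.
#' @param subject_col_map,trial_col_map Optional named character vectors
#'   mapping canonical column names (names) to the file's column names
#'   (values).
#' @param duration_per_lap If `TRUE`, circle rows carry the per-lap
#'   duration and total durations are reconstructed as `laps * duration`.
#' @param provenance Provenance record; defaults to the file paths.
#' @return A `walk_cohort`.
#' @export
read_cohort <- function(subjects_path, trials_path,
                        subject_col_map = NULL, trial_col_map = NULL,
                        duration_per_lap = FALSE, provenance = NULL) {
  apply_map <- function(df, map) {
    if (is.null(map)) return(df)
    for (canon in names(map)) {
      if (!map[[canon]] %in% names(df))
        stop("mapped column '", map[[canon]], "' not found", call. = FALSE)
      names(df)[names(df) == map[[canon]]] <- canon
    }
    df
  }
  subjects <- apply_map(utils::read.csv(subjects_path,
                                        stringsAsFactors = FALSE),
                        subject_col_map)
  trials <- apply_map(utils::read.csv(trials_path, stringsAsFactors = FALSE),
                      trial_col_map)
  if (!is.numeric(trials$duration_s))
    stop("non-numeric trial durations in ", trials_path, "; row(s): ",
         paste(utils::head(which(is.na(suppressWarnings(
           as.numeric(trials$duration_s)))), 5), collapse = ", "),
         call. = FALSE)
  if (duration_per_lap) {
    is_c <- trials$task == "circle"
    trials$duration_s[is_c] <- trials$duration_s[is_c] * trials$laps[is_c]
  }
  if (is.null(provenance))
    provenance <- list(type = "real",
                       source = c(subjects = subjects_path,
                                  trials = trials_path))
  new_cohort(subjects, trials, provenance)
}

#' Write a cohort as two CSV files (plus a config sidecar)
#'
#' @param cohort A `walk_cohort`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"cohort"`).
#' @return Named list of paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  stopifnot(inherits(cohort, "walk_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ps <- file.path(dir, paste0(prefix, "_subjects.csv"))
  pt <- file.path(dir, paste0(prefix, "_trials.csv"))
  utils::write.csv(cohort$subjects, ps, row.names = FALSE)
  tr <- cohort$trials
  tr$speed <- NULL  # derived on load
  utils::write.csv(tr, pt, row.names = FALSE)
  paths <- list(subjects = ps, trials = pt)
  if (identical(cohort$provenance$type, "synthetic")) {
    pc <- file.path(dir, paste0(prefix, "_config.json"))
    cfg <- cohort$provenance$config
    ser <- lapply(unclass(cfg), function(x) {
      if (inherits(x, "walk_eff")) unclass(x)
      else if (is.list(x)) lapply(x, unclass)
      else x
    })
    jsonlite::write_json(ser, pc, auto_unbox = TRUE, digits = NA)
    paths$config <- pc
  }
  invisible(paths)
}

serialize_test <- function(r) {
  if (isTRUE(r$skipped)) return(list(name = r$name, skipped = TRUE,
                                     reason = r$reason))
  c(list(skipped = FALSE), unclass(r)[c(
    "name", "method", "statistic", "p_raw", "p_bonferroni", "p_t_raw",
    "p_t_bonferroni", "n_tests", "n_boot", "seed", "n", "direction",
    "degenerate", "floored", "post_hoc")])
}

serialize_fit <- function(f) {
  list(version = f$spec$version, group = f$spec$group,
       coeffs = unclass(f$coeffs)[c("a0", "a1", "a2", "a_change", "a_turn")],
       free = f$spec$free, mse = f$mse, n_trials = f$n_trials,
       grid_validated = f$grid_validated, grid_best_mse = f$grid_best_mse)
}

model_curves <- function(coeffs, eff, distances, radii, fraction = 0.01) {
  straight <- lapply(distances, function(d) {
    v <- optimal_speed_straight(coeffs, d, eff)
    b <- near_optimal_band(function(u) bout_total_cost(coeffs, d, u, eff),
                           v, fraction)
    list(distance_m = d, v_opt = v, v_lo = b$v_lo, v_hi = b$v_hi)
  })
  circle <- lapply(radii, function(r) {
    v <- optimal_speed_circle(coeffs, r)
    b <- near_optimal_band(function(u) circle_cost_per_distance(coeffs, u, r),
                           v, fraction)
    list(radius_m = r, v_opt = v, v_lo = b$v_lo, v_hi = b$v_hi)
  })
  list(fraction = fraction, straight = straight, circle = circle)
}

#' Run the full analysis pipeline on a cohort
#'
#' Chains the whole analysis: per-condition subject means, percent speed
#' reductions (all subjects and per amputation level), the pre-registered
#' hypothesis battery plus the post hoc direction contrast, the
#' fixed-effects speed-distance (4-10 m) and speed-radius linear fits, and
#' inverse-optimization fits (requested versions, per group) with grid
#' validation and the implied model curves with near-optimal speed bands.
#'
#' @param cohort A `walk_cohort`; if `NULL` one is generated from
#'   `synth_config`.
#' @param synth_config [synthetic_config()] used when `cohort` is `NULL`.
#' @param fit_versions Inverse-optimization versions to run (subset of 1:2).
#' @param groups Amputation groups to fit.
#' @param n_boot Bootstrap resamples for the battery.
#' @param seed Seed for the battery resampling.
#' @param eff [efficiency_params()].
#' @param out_dir If non-NULL, the report is written as `report.json` and a
#'   plain-text `run.log` there.
#' @return The report, an S3-free nested list (JSON-ready).
#' @export
run_pipeline <- function(cohort = NULL, synth_config = synthetic_config(),
                         fit_versions = c(1, 2),
                         groups = c("above_knee", "below_knee"),
                         n_boot = 1e5, seed = 1,
                         eff = efficiency_params(), out_dir = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(synth_config)
  stopifnot(inherits(cohort, "walk_cohort"))
  means <- subject_condition_means(cohort)
  reductions <- percent_reduction(cohort)
  battery <- run_hypothesis_battery(cohort, n_boot = n_boot, seed = seed)

  dist_dat <- means[means$task == "straight" &
                      means$condition >= 4 & means$condition <= 10, ]
  rad_dat <- means[means$task == "circle" & means$direction %in% "pooled", ]
  linfits <- list()
  if (length(unique(dist_dat$condition)) >= 2)
    linfits$distance <- linear_fit_subject_offsets(
      data.frame(subject_id = dist_dat$subject_id,
                 predictor = dist_dat$condition,
                 speed = dist_dat$mean_speed))
  if (length(unique(rad_dat$condition)) >= 2)
    linfits$radius <- linear_fit_subject_offsets(
      data.frame(subject_id = rad_dat$subject_id,
                 predictor = rad_dat$condition,
                 speed = rad_dat$mean_speed))

  subjects <- cohort_subjects(cohort)
  trials <- cohort_trials(cohort)
  fits <- list()
  curves <- list()
  for (g in groups) {
    ids <- subjects$subject_id[subjects$level == level_from_group(g)]
    g_trials <- trials[trials$subject_id %in% ids, ]
    if (!nrow(g_trials)) {
      fits[[g]] <- list(skipped = TRUE, reason = "no trials for group")
      next
    }
    for (ver in fit_versions) {
      fit <- fit_coefficients(fit_spec(ver, g), g_trials, eff)
      fits[[g]][[paste0("version", ver)]] <- serialize_fit(fit)
      curves[[g]][[paste0("version", ver)]] <- model_curves(
        fit$coeffs, eff,
        distances = sort(unique(g_trials$distance_m[g_trials$task == "straight"])),
        radii = sort(unique(g_trials$radius_m[g_trials$task == "circle"])))
    }
  }

  report <- list(
    provenance = cohort$provenance["type"],
    n_subjects = nrow(subjects),
    n_trials = nrow(trials),
    settings = list(eta_pos = eff$eta_pos, eta_neg = eff$eta_neg,
                    n_boot = n_boot, seed = seed,
                    bonferroni_family = 10,
                    fit_versions = fit_versions),
    condition_means = means,
    percent_reduction = reductions,
    hypothesis_tests = lapply(battery, serialize_test),
    linear_fits = lapply(linfits, function(f)
      unclass(f)[c("slope", "adjusted_r2", "p_slope", "t_slope", "df",
                   "conditions_used", "n")]),
    inverse_optimization = fits,
    model_curves = curves)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(c(
      sprintf("walkopt %s", as.character(utils::packageVersion("walkopt"))),
      sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      sprintf("seed: %d  n_boot: %g", seed, n_boot),
      sprintf("cohort: %s (%d subjects, %d trials)",
              cohort$provenance$type, nrow(subjects), nrow(trials))),
      file.path(out_dir, "run.log"))
  }
  report
}
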