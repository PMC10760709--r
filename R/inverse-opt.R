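#' Specification of an inverse-optimization fit
#'
#' Two fit versions are supported. Version 1 holds all steady-rate
#' coefficients fixed and estimates only the changing-speed and turning
#' coefficients (`a_change`, `a_turn`). Version 2 additionally frees `a2`,
#' letting the quadratic speed dependence absorb population differences or
#' non-energetic velocity-dependent costs. `a0` and `a1` are never fitted:
#' the optimal speeds are invariant to an overall scaling of the cost and do
#' not involve `a1` at all, so neither is identifiable from speeds.
#'
#' @param version 1 or 2.
#' @param group Population group the trials come from
#'   (`"above_knee"`, `"below_knee"` or `"none"`).
#' @param fixed A `walk_coeffs` object supplying the held-fixed coefficients
#'   (default: the literature steady-rate set for `group`).
#' @param start_points Optional matrix of starting values (one row per
#'   start, columns named after the free coefficients). Default: five
#'   points spanning the validation grid ranges.
#' @param grid Named list of `c(min, max, step)` vectors for the validation
#'   grid. Defaults: `a_change` in \[0, 10\] step 0.01, `a_turn` in
#'   \[0, 20\] step 0.02, `a2` in \[0.5, 10\] step 0.01.
#' @return An object of class `walk_fit_spec`.
#' @export
fit_spec <- function(version = 1,
                     group = c("above_knee", "below_knee", "none"),
                     fixed = steady_coefficients(group),
                     start_points = NULL, grid = NULL) {
  group <- match.arg(group)
  if (!version %in% c(1, 2)) stop("'version' must be 1 or 2", call. = FALSE)
  stopifnot(inherits(fixed, "walk_coeffs"))
  free <- if (version == 1) c("a_change", "a_turn") else
    c("a2", "a_change", "a_turn")
  default_grid <- list(a_change = c(0, 10, 0.01),
                       a_turn   = c(0, 20, 0.02),
                       a2       = c(0.5, 10, 0.01))
  if (!is.null(grid)) default_grid[names(grid)] <- grid
  grid <- default_grid[free]
  if (is.null(start_points)) {
    q <- c(0.05, 0.25, 0.5, 0.75, 0.95)
    start_points <- sapply(free, function(nm) {
      g <- grid[[nm]]
      pmax(g[1] + q * (g[2] - g[1]), 1e-3)
    })
    start_points <- matrix(start_points, nrow = length(q),
                           dimnames = list(NULL, free))
  }
  structure(list(version = version, group = group, fixed = fixed,
                 free = free, start_points = start_points, grid = grid),
            class = "walk_fit_spec")
}

check_trials <- function(trials, need_speed = FALSE) {
  stopifnot(is.data.frame(trials))
  req <- c("task", "distance_m", "radius_m")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trials are missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  is_s <- trials$task == "straight"
  is_c <- trials$task == "circle"
  if (any(!(is_s | is_c)))
    stop("every trial must have task 'straight' or 'circle'", call. = FALSE)
  if (any(is_s & !is.finite(trials$distance_m)) ||
      any(is_c & !is.finite(trials$radius_m)))
    stop("each trial needs its distance (straight) or radius (circle)",
         call. = FALSE)
  if (need_speed && (!"speed" %in% names(trials) ||
                     any(!is.finite(trials$speed))))
    stop("trials must carry a finite observed 'speed' column", call. = FALSE)
  invisible(trials)
}

#' Model-predicted optimal speeds for a set of trials
#'
#' Straight bouts get the implicit-equation optimum for their distance;
#' circle trials get the closed-form optimum for their radius. Predictions
#' depend only on the trial's condition, so they are computed once per
#' unique distance/radius and mapped back in input order.
#'
#' @param coeffs A `walk_coeffs` object.
#' @param trials Data frame with columns `task` (`"straight"`/`"circle"`),
#'   `distance_m`, `radius_m`.
#' @param eff [efficiency_params()].
#' @return Numeric vector of predicted speeds, m/s, aligned with `trials`.
#' @export
predict_speeds <- function(coeffs, trials, eff = efficiency_params()) {
  check_trials(trials)
  n <- nrow(trials)
  out <- numeric(n)
  if (n == 0L) return(out)
  is_s <- trials$task == "straight"
  if (any(is_s)) {
    du <- sort(unique(trials$distance_m[is_s]))
    vu <- optimal_speed_straight(coeffs, du, eff)
    out[is_s] <- vu[match(trials$distance_m[is_s], du)]
  }
  if (any(!is_s)) {
    ru <- sort(unique(trials$radius_m[!is_s]))
    vu <- optimal_speed_circle(coeffs, ru)
    out[!is_s] <- vu[match(trials$radius_m[!is_s], ru)]
  }
  out
}

#' Mean squared error between predicted and observed speeds
#'
#' Mean over all trials — straight bouts and circle trials pooled — of the
#' squared difference between the model-predicted optimal speed and the
#' observed preferred speed. Trials are weighted equally, so conditions with
#' more trials weigh more.
#'
#' @inheritParams predict_speeds
#' @param trials Data frame as in [predict_speeds()] plus an observed
#'   `speed` column (m/s).
#' @return MSE in (m/s)^2.
#' @export
speed_mse <- function(coeffs, trials, eff = efficiency_params()) {
  check_trials(trials, need_speed = TRUE)
  if (nrow(trials) == 0L) stop("need at least one trial", call. = FALSE)
  mean((predict_speeds(coeffs, trials, eff) - trials$speed)^2)
}

# per-condition sufficient statistics: SSE for any prediction vector is
# sum_d (n_d p_d^2 - 2 p_d S_d + Q_d)
condition_stats <- function(values, speeds) {
  u <- sort(unique(values))
  list(u = u,
       n = vapply(u, function(x) sum(values == x), numeric(1)),
       S = vapply(u, function(x) sum(speeds[values == x]), numeric(1)),
       Q = vapply(u, function(x) sum(speeds[values == x]^2), numeric(1)))
}

sse_from_pred <- function(st, pred) sum(st$n * pred^2 - 2 * pred * st$S + st$Q)

#' Fit cost coefficients by inverse optimization
#'
#' Finds the free coefficients whose implied optimal speeds minimise the
#' mean squared error against observed trial speeds ([speed_mse()]).
#' The free coefficients are optimised on the log scale (enforcing
#' positivity) by Nelder-Mead from each start point in the spec; the best
#' converged solution is kept and then checked against an exhaustive grid
#' with [grid_validate()].
#'
#' Identifiability requires at least one straight bout for `a_change` and at
#' least one circle trial for `a_turn`; violations raise an error naming the
#' unidentifiable coefficient.
#'
#' @param spec A [fit_spec()].
#' @param trials Trial data frame with observed `speed`.
#' @param eff [efficiency_params()].
#' @param validate Run [grid_validate()] on the result (default TRUE).
#' @return An object of class `walk_fit`: fitted `coeffs` (free + fixed
#'   merged), `mse`, `n_trials`, the `spec`, per-start convergence codes,
#'   and grid-validation fields.
#' @export
fit_coefficients <- function(spec, trials, eff = efficiency_params(),
                             validate = TRUE) {
  stopifnot(inherits(spec, "walk_fit_spec"))
  check_trials(trials, need_speed = TRUE)
  n_straight <- sum(trials$task == "straight")
  n_circle <- sum(trials$task == "circle")
  if ("a_change" %in% spec$free && n_straight == 0L)
    stop("'a_change' is unidentifiable: no straight bouts in the trials",
         call. = FALSE)
  if ("a_turn" %in% spec$free && n_circle == 0L)
    stop("'a_turn' is unidentifiable: no circle trials in the trials",
         call. = FALSE)

  obj <- function(logpar) {
    cf <- modify_coefficients(spec$fixed,
                              as.list(stats::setNames(exp(logpar), spec$free)))
    speed_mse(cf, trials, eff)
  }
  runs <- apply(spec$start_points, 1L, function(st) {
    stats::optim(log(pmax(st, 1e-8)), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  # polish: restart the simplex at the incumbent
  best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
  if (best2$value < best$value) best <- best2

  coeffs <- modify_coefficients(
    spec$fixed, as.list(stats::setNames(exp(best$par), spec$free)))
  fit <- structure(list(
    spec = spec, coeffs = coeffs, mse = best$value,
    n_trials = nrow(trials), n_straight = n_straight, n_circle = n_circle,
    convergence = vapply(runs, `[[`, numeric(1), "convergence"),
    grid_validated = NA, grid_best_mse = NA_real_,
    grid_best = NULL), class = "walk_fit")
  if (validate) fit <- grid_validate(fit, trials, eff)
  fit
}

#' Validate a fitted optimum against an exhaustive coefficient grid
#'
#' Evaluates the MSE on a fine grid of the free coefficients (spec grids:
#' `a_change` step 0.01, `a_turn` step 0.02, `a2` step 0.01) and records the
#' best grid value; the fit is validated when no grid point beats the
#' optimiser's MSE (within 1e-12). The full resolution is reached by a
#' coarse pass at 10x the step followed by a 10x refinement around the
#' incumbent. Because `a_change` affects only straight-bout predictions and
#' `a_turn` only circle predictions (given `a2`), the 2-D/3-D grid minimum
#' decomposes exactly into 1-D sweeps, which is what makes the exhaustive
#' scan affordable.
#'
#' @param fit A `walk_fit` from [fit_coefficients()].
#' @param trials The trials the fit used.
#' @param eff [efficiency_params()].
#' @return The fit with `grid_validated`, `grid_best_mse`, `grid_best`
#'   filled in. If the fitted optimum lies outside the grid bounds a warning
#'   is raised and validation is marked inconclusive (`NA`).
#' @export
grid_validate <- function(fit, trials, eff = efficiency_params()) {
  stopifnot(inherits(fit, "walk_fit"))
  check_trials(trials, need_speed = TRUE)
  spec <- fit$spec
  grid <- spec$grid
  fitted_free <- unlist(fit$coeffs[spec$free])
  out_of_bounds <- any(fitted_free < vapply(grid, `[`, numeric(1), 1) |
                       fitted_free > vapply(grid, `[`, numeric(1), 2))
  if (out_of_bounds) {
    warning("fitted optimum lies outside the validation grid bounds; ",
            "validation inconclusive", call. = FALSE)
    fit$grid_validated <- NA
    return(fit)
  }

  is_s <- trials$task == "straight"
  st_s <- if (any(is_s)) condition_stats(trials$distance_m[is_s],
                                         trials$speed[is_s]) else NULL
  st_c <- if (any(!is_s)) condition_stats(trials$radius_m[!is_s],
                                          trials$speed[!is_s]) else NULL
  n_tot <- nrow(trials)

  seq_grid <- function(g, step) seq(g[1], g[2], by = step)
  # straight-bout SSE swept over a_change for one a2
  sweep_change <- function(a2, a_ch_vals) {
    if (is.null(st_s)) return(list(sse = rep(0, length(a_ch_vals)),
                                   best = a_ch_vals[1]))
    sse <- vapply(a_ch_vals, function(ac) {
      cf <- modify_coefficients(spec$fixed, list(a2 = a2, a_change = ac))
      sse_from_pred(st_s, optimal_speed_straight(cf, st_s$u, eff))
    }, numeric(1))
    list(sse = sse, best = a_ch_vals[which.min(sse)], min = min(sse))
  }
  # circle SSE swept over a_turn for one a2 (closed form, vectorised)
  sweep_turn <- function(a2, a_t_vals) {
    if (is.null(st_c)) return(list(sse = rep(0, length(a_t_vals)),
                                   best = a_t_vals[1]))
    sse <- vapply(a_t_vals, function(at) {
      pred <- sqrt(spec$fixed$a0 / (a2 + at / st_c$u^2))
      sse_from_pred(st_c, pred)
    }, numeric(1))
    list(sse = sse, best = a_t_vals[which.min(sse)], min = min(sse))
  }
  eval_a2 <- function(a2, ch_vals, t_vals) {
    sw_c <- sweep_change(a2, ch_vals)
    sw_t <- sweep_turn(a2, t_vals)
    list(sse = min(sw_c$sse) + min(sw_t$sse),
         a_change = sw_c$best, a_turn = sw_t$best)
  }

  coarse <- lapply(grid, function(g) seq_grid(g, 10 * g[3]))
  a2_vals <- if (spec$version == 2) coarse$a2 else spec$fixed$a2
  pass <- lapply(a2_vals, eval_a2, ch_vals = coarse$a_change,
                 t_vals = coarse$a_turn)
  i <- which.min(vapply(pass, `[[`, numeric(1), "sse"))
  inc <- c(a2 = a2_vals[i], a_change = pass[[i]]$a_change,
           a_turn = pass[[i]]$a_turn)

  refine_vals <- function(nm, centre) {
    g <- grid[[nm]]
    seq_grid(c(max(g[1], centre - 10 * g[3]),
               min(g[2], centre + 10 * g[3]), g[3]), g[3])
  }
  a2_fine <- if (spec$version == 2) refine_vals("a2", inc[["a2"]]) else
    spec$fixed$a2
  pass2 <- lapply(a2_fine, eval_a2,
                  ch_vals = refine_vals("a_change", inc[["a_change"]]),
                  t_vals = refine_vals("a_turn", inc[["a_turn"]]))
  j <- which.min(vapply(pass2, `[[`, numeric(1), "sse"))
  best_sse <- min(pass2[[j]]$sse, pass[[i]]$sse)
  fit$grid_best_mse <- best_sse / n_tot
  fit$grid_best <- c(if (spec$version == 2) c(a2 = a2_fine[j]),
                     a_change = pass2[[j]]$a_change,
                     a_turn = pass2[[j]]$a_turn)
  fit$grid_validated <- fit$mse <= fit$grid_best_mse + 1e-12
  fit
}

#' @export
print.walk_fit <- function(x, ...) {
  cat(sprintf("Inverse-optimization fit (version %d, group %s)\n",
              x$spec$version, x$spec$group))
  cat(sprintf("  free: %s\n", paste(
    sprintf("%s = %.4g", x$spec$free, unlist(x$coeffs[x$spec$free])),
    collapse = ", ")))
  cat(sprintf("  MSE = %.6g (m/s)^2 over %d trials (%d straight, %d circle)\n",
              x$mse, x$n_trials, x$n_straight, x$n_circle))
  if (!is.na(x$grid_validated))
    cat(sprintf("  grid validation: %s (grid best MSE %.6g)\n",
                if (x$grid_validated) "passed" else "FAILED", x$grid_best_mse))
  invisible(x)
}
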