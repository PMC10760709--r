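#' Steady-state metabolic rate of walking
#'
#' Quadratic model of the mass-normalised metabolic rate at constant speed,
#' `a0 + a1*v + a2*v^2` (W/kg).
#'
#' @param coeffs A [cost_coefficients()] object.
#' @param v Walking speed, m/s. Vectorised; must be >= 0.
#' @return Metabolic rate, W/kg.
#' @export
#' @examples
#' steady_rate(steady_coefficients("none"), 1.3)
steady_rate <- function(coeffs, v) {
  stopifnot(inherits(coeffs, "walk_coeffs"))
  if (any(!is.finite(v)) || any(v < 0))
    stop("speed 'v' must be finite and >= 0", call. = FALSE)
  coeffs$a0 + coeffs$a1 * v + coeffs$a2 * v^2
}

#' Total metabolic cost of a short straight walking bout
#'
#' A bout of distance `D` is modelled as an instantaneous acceleration to
#' speed `v`, steady walking for the whole distance, and an instantaneous
#' stop. The total mass-normalised cost (J/kg) is the steady cost plus the
#' start-stop cost:
#' `(a0 + a1 v + a2 v^2) D / v  +  a_change * (1/eta_pos + 1/eta_neg) * v^2 / 2`.
#' The kinetic-energy term is per unit body mass, consistent with the W/kg
#' steady coefficients.
#'
#' @inheritParams steady_rate
#' @param D Bout distance, m, > 0.
#' @param eff [efficiency_params()] for the start-stop term.
#' @return Energy per body mass, J/kg. Vectorised over `v` (and `D`).
#' @export
bout_total_cost <- function(coeffs, D, v, eff = efficiency_params()) {
  stopifnot(inherits(coeffs, "walk_coeffs"), inherits(eff, "walk_eff"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("'D' must be > 0", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("speed 'v' must be > 0 (the bout cost diverges at v = 0)",
         call. = FALSE)
  steady_rate(coeffs, v) * D / v + coeffs$a_change * eff$k * v^2 / 2
}

#' Energy-optimal speed for a straight bout of given distance
#'
#' The minimiser of [bout_total_cost()] over speed. At the optimum the speed
#' satisfies the implicit relation
#' `a_change * v^3 * (1/eta_pos + 1/eta_neg) / (a0 - a2 v^2) = D`,
#' whose unique root lies in `(0, sqrt(a0/a2))`; the left side is strictly
#' increasing there, so the root is found by safeguarded bracketing
#' (`uniroot` on `(1e-9, sqrt(a0/a2) - 1e-9)`, tol 1e-10). When
#' `a_change = 0` the start-stop term vanishes and the optimum is the
#' minimiser of cost per distance, `sqrt(a0/a2)`, for every distance.
#'
#' @inheritParams bout_total_cost
#' @param D Bout distance(s), m, > 0. Vectorised.
#' @return Optimal speed(s), m/s; strictly increasing in `D` and bounded
#'   above by `sqrt(a0/a2)`.
#' @export
#' @examples
#' optimal_speed_straight(reference_coefficients("none"), c(4, 6, 8, 10, 23))
optimal_speed_straight <- function(coeffs, D, eff = efficiency_params()) {
  stopifnot(inherits(coeffs, "walk_coeffs"), inherits(eff, "walk_eff"))
  if (any(!is.finite(D)) || any(D <= 0)) stop("'D' must be > 0", call. = FALSE)
  v_max <- sqrt(coeffs$a0 / coeffs$a2)
  if (coeffs$a_change == 0) return(rep(v_max, length(D)))
  ak <- coeffs$a_change * eff$k
  eps <- 1e-9
  vapply(D, function(d) {
    f <- function(v) ak * v^3 / (coeffs$a0 - coeffs$a2 * v^2) - d
    lo <- eps
    hi <- v_max - eps
    if (f(hi) < 0)  # denominator underflow pathologies only; widen toward v_max
      stop(sprintf(
        "optimal-speed bracket failed for D = %g: f(%.12g) = %g, f(%.12g) = %g",
        d, lo, f(lo), hi, f(hi)), call. = FALSE)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Metabolic cost per distance for circle walking
#'
#' Walking a circle of radius `R` at tangential speed `v` adds a turning
#' rate cost `a_turn * (v/R)^2` to the steady quadratic rate; the cost per
#' unit distance (J/kg/m) is `a0/v + a1 + a2 v + a_turn v / R^2`.
#'
#' @inheritParams steady_rate
#' @param R Circle radius, m, > 0.
#' @return Energy per distance per mass, J/kg/m. Vectorised over `v`.
#' @export
circle_cost_per_distance <- function(coeffs, v, R) {
  stopifnot(inherits(coeffs, "walk_coeffs"))
  if (any(!is.finite(v)) || any(v <= 0)) stop("'v' must be > 0", call. = FALSE)
  if (any(is.na(R)) || any(R <= 0)) stop("'R' must be > 0", call. = FALSE)
  coeffs$a0 / v + coeffs$a1 + coeffs$a2 * v + coeffs$a_turn * v / R^2
}

#' Energy-optimal tangential speed for circle walking
#'
#' Closed-form minimiser of [circle_cost_per_distance()]:
#' `sqrt(a0 / (a2 + a_turn / R^2))`. Strictly increasing in `R` and bounded
#' above by the straight-line optimum `sqrt(a0/a2)` (attained as R -> Inf).
#'
#' @inheritParams circle_cost_per_distance
#' @param R Circle radius (or radii), m, > 0. Vectorised.
#' @return Optimal tangential speed(s), m/s.
#' @export
optimal_speed_circle <- function(coeffs, R) {
  stopifnot(inherits(coeffs, "walk_coeffs"))
  if (any(!is.finite(R) & !is.infinite(R)) || any(R <= 0))
    stop("'R' must be > 0", call. = FALSE)
  sqrt(coeffs$a0 / (coeffs$a2 + coeffs$a_turn / R^2))
}

#' Band of speeds within a fraction of the minimum cost
#'
#' Energy landscapes near the optimal walking speed are flat, so speeds whose
#' cost exceeds the minimum by less than e.g. 1% are practically
#' indistinguishable from optimal. Given a unimodal one-argument cost curve
#' and its minimiser, this solves `cost(v) = (1 + fraction) * cost(v_opt)` on
#' each side by bracketed root finding (geometric bracket expansion, then
#' `uniroot` with tol 1e-8).
#'
#' @param cost_curve Function of speed only, unimodal around `v_opt`.
#' @param v_opt The minimising speed, m/s.
#' @param fraction Allowed relative cost excess (default 0.01 = 1%).
#' @param v_max Upper search limit for the high side; if the cost never
#'   exceeds the threshold before `v_max` the band is reported open-ended
#'   (`v_hi = Inf`). Default `10 * v_opt`.
#' @return An object of class `speed_band`: list with `v_opt`, `v_lo`,
#'   `v_hi`, `fraction`.
#' @export
#' @examples
#' cf <- reference_coefficients("below_knee")
#' v <- optimal_speed_circle(cf, 2)
#' near_optimal_band(function(u) circle_cost_per_distance(cf, u, 2), v)
near_optimal_band <- function(cost_curve, v_opt, fraction = 0.01,
                              v_max = 10 * v_opt) {
  stopifnot(is.function(cost_curve), is.numeric(v_opt), v_opt > 0,
            is.numeric(fraction), fraction >= 0)
  c_min <- cost_curve(v_opt)
  if (fraction == 0)
    return(structure(list(v_opt = v_opt, v_lo = v_opt, v_hi = v_opt,
                          fraction = 0), class = "speed_band"))
  thr <- (1 + fraction) * c_min
  g <- function(v) cost_curve(v) - thr

  # low side: shrink geometrically until the cost exceeds the threshold
  lo <- v_opt / 2
  while (g(lo) < 0 && lo > v_opt * 1e-12) lo <- lo / 2
  v_lo <- if (g(lo) < 0) 0 else
    stats::uniroot(g, c(lo, v_opt), tol = 1e-8)$root

  # high side: expand geometrically up to v_max
  hi <- v_opt * 1.5
  while (hi < v_max && g(hi) < 0) hi <- hi * 1.5
  v_hi <- if (g(min(hi, v_max)) < 0) Inf else
    stats::uniroot(g, c(v_opt, min(hi, v_max)), tol = 1e-8)$root

  structure(list(v_opt = v_opt, v_lo = v_lo, v_hi = v_hi,
                 fraction = fraction), class = "speed_band")
}

#' @export
print.speed_band <- function(x, ...) {
  cat(sprintf("Speed band within %.3g%% of minimum cost: [%.4g, %.4g] m/s (optimum %.4g)\n",
              100 * x$fraction, x$v_lo, x$v_hi, x$v_opt))
  invisible(x)
}
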