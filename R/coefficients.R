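#' Metabolic cost coefficients for one population group
#'
#' Bundles the five parameters of the walking cost model, all mass-normalised:
#' the quadratic steady-rate coefficients `a0 + a1*v + a2*v^2` (W/kg, speed in
#' m/s), the dimensionless scaling `a_change` on the start-stop kinetic-energy
#' cost, and the turning coefficient `a_turn` (W/kg per (1/s)^2) multiplying
#' the squared angular rate `(v/R)^2`.
#'
#' `a1` may be negative (it is for both amputation groups in the literature);
#' `a0` and `a2` must be positive so the cost per distance is U-shaped, and
#' `a_change`, `a_turn` must be non-negative.
#'
#' @param a0 Metabolic rate offset, W/kg. Must be > 0.
#' @param a1 Linear speed coefficient, W/kg per (m/s). May be negative.
#' @param a2 Quadratic speed coefficient, W/kg per (m/s)^2. Must be > 0.
#' @param a_change Dimensionless scaling on the start-stop work cost, >= 0.
#' @param a_turn Turning cost coefficient, W/kg per (1/s)^2, >= 0.
#' @param group Population label: `"above_knee"`, `"below_knee"` or `"none"`.
#' @return An object of class `walk_coeffs` (a named list).
#' @seealso [steady_coefficients()], [reference_coefficients()]
#' @export
#' @examples
#' cost_coefficients(2.22, 0, 1.115, a_change = 1.34, a_turn = 1.11)
cost_coefficients <- function(a0, a1 = 0, a2, a_change = 0, a_turn = 0,
                              group = c("none", "below_knee", "above_knee")) {
  group <- match.arg(group)
  for (nm in c("a0", "a1", "a2", "a_change", "a_turn")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (a0 <= 0) stop("'a0' must be > 0", call. = FALSE)
  if (a2 <= 0) stop("'a2' must be > 0", call. = FALSE)
  if (a_change < 0) stop("'a_change' must be >= 0", call. = FALSE)
  if (a_turn < 0) stop("'a_turn' must be >= 0", call. = FALSE)
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 a_change = a_change, a_turn = a_turn, group = group),
            class = "walk_coeffs")
}

#' @export
print.walk_coeffs <- function(x, ...) {
  cat(sprintf(
    "Walking cost coefficients [%s]\n  a0 = %.4g W/kg, a1 = %.4g, a2 = %.4g\n  a_change = %.4g, a_turn = %.4g W/kg per (1/s)^2\n",
    x$group, x$a0, x$a1, x$a2, x$a_change, x$a_turn))
  invisible(x)
}

#' Steady-rate coefficients from the treadmill literature
#'
#' Quadratic steady walking rate coefficients measured by indirect calorimetry
#' in earlier treadmill studies, per population group: above-knee amputation
#' (4.97, -5.98, 5.62), below-knee amputation (3.64, -2.19, 2.89) and no
#' amputation (2.22, 0, 1.115), in W/kg with speed in m/s. The changing-speed
#' and turning coefficients are zero; merge fitted or reference values with
#' [modify_coefficients()] or use [reference_coefficients()].
#'
#' @param group `"above_knee"`, `"below_knee"` or `"none"`.
#' @return A `walk_coeffs` object with `a_change = a_turn = 0`.
#' @export
steady_coefficients <- function(group = c("none", "below_knee", "above_knee")) {
  group <- match.arg(group)
  tab <- list(
    above_knee = c(a0 = 4.97, a1 = -5.98, a2 = 5.62),
    below_knee = c(a0 = 3.64, a1 = -2.19, a2 = 2.89),
    none       = c(a0 = 2.22, a1 = 0,     a2 = 1.115))
  a <- tab[[group]]
  cost_coefficients(a[["a0"]], a[["a1"]], a[["a2"]], 0, 0, group = group)
}

#' Reference coefficient sets including changing-speed and turning costs
#'
#' The steady-rate literature coefficients of [steady_coefficients()] merged
#' with published inverse-optimization estimates of `a_change` and `a_turn`
#' for each group. Version 1 keeps the literature `a2`; version 2 uses the
#' jointly refitted `a2`. These are convenient generating truths for the
#' synthetic cohort generator and starting references for fits.
#'
#' @param group `"above_knee"`, `"below_knee"` or `"none"`.
#' @param version 1 (a2 held at its literature value) or 2 (a2 refit).
#' @return A `walk_coeffs` object.
#' @export
reference_coefficients <- function(group = c("none", "below_knee", "above_knee"),
                                   version = 1) {
  group <- match.arg(group)
  if (!version %in% c(1, 2)) stop("'version' must be 1 or 2", call. = FALSE)
  base <- steady_coefficients(group)
  v1 <- list(above_knee = c(a_change = 2.67, a_turn = 7.71),
             below_knee = c(a_change = 2.65, a_turn = 6.64),
             none       = c(a_change = 1.34, a_turn = 1.11))
  v2 <- list(above_knee = c(a2 = 6.12, a_change = 1.84, a_turn = 6.53),
             below_knee = c(a2 = 3.66, a_change = 1.41, a_turn = 4.26),
             none       = c(a2 = 1.19, a_change = 1.30, a_turn = 1.04))
  upd <- if (version == 1) v1[[group]] else v2[[group]]
  modify_coefficients(base, as.list(upd))
}

#' Replace selected coefficients in a `walk_coeffs` object
#'
#' @param coeffs A `walk_coeffs` object.
#' @param updates Named list with any of `a0`, `a1`, `a2`, `a_change`, `a_turn`.
#' @return A new `walk_coeffs` object (invariants re-checked).
#' @export
modify_coefficients <- function(coeffs, updates) {
  stopifnot(inherits(coeffs, "walk_coeffs"))
  bad <- setdiff(names(updates), c("a0", "a1", "a2", "a_change", "a_turn"))
  if (length(bad)) stop("unknown coefficient name(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  x <- unclass(coeffs)
  x[names(updates)] <- updates
  cost_coefficients(x$a0, x$a1, x$a2, x$a_change, x$a_turn, group = x$group)
}

#' Muscle work efficiency parameters for the start-stop cost
#'
#' Positive and negative mechanical work by muscle costs metabolic energy at
#' approximately 1/eta_pos and 1/eta_neg times the work done; the start-stop
#' cost scales the kinetic-energy change by `k = 1/eta_pos + 1/eta_neg`.
#' Defaults are the standard values eta_pos = 0.25, eta_neg = 1.2.
#'
#' @param eta_pos Positive-work efficiency, dimensionless, > 0.
#' @param eta_neg Negative-work efficiency, dimensionless, > 0.
#' @return An object of class `walk_eff` with fields `eta_pos`, `eta_neg`
#'   and the derived `k`.
#' @export
efficiency_params <- function(eta_pos = 0.25, eta_neg = 1.2) {
  if (!is.numeric(eta_pos) || length(eta_pos) != 1L || eta_pos <= 0)
    stop("'eta_pos' must be a single positive number", call. = FALSE)
  if (!is.numeric(eta_neg) || length(eta_neg) != 1L || eta_neg <= 0)
    stop("'eta_neg' must be a single positive number", call. = FALSE)
  structure(list(eta_pos = eta_pos, eta_neg = eta_neg,
                 k = 1 / eta_pos + 1 / eta_neg),
            class = "walk_eff")
}

group_from_level <- function(level) {
  c(BK = "below_knee", AK = "above_knee")[[level]]
}

level_from_group <- function(group) {
  c(below_knee = "BK", above_knee = "AK")[[group]]
}
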