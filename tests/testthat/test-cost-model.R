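test_that("steady rate follows the quadratic model at the literature coefficients", {
  none <- steady_coefficients("none")
  expect_equal(steady_rate(none, 0), 2.22)
  expect_equal(steady_rate(none, 1), 3.335)
  ak <- steady_coefficients("above_knee")
  expect_equal(steady_rate(ak, 1), 4.97 - 5.98 + 5.62)
  expect_error(steady_rate(none, -0.1), ">= 0")
})

test_that("bout cost is steady cost plus the start-stop kinetic term", {
  none <- steady_coefficients("none")
  v <- seq(0.2, 2, by = 0.3)
  # no changing-speed cost: total is rate * time
  expect_equal(bout_total_cost(none, 7, v), steady_rate(none, v) * 7 / v)
  cf <- modify_coefficients(none, list(a_change = 1.34))
  expect_equal(bout_total_cost(cf, 10, 1),
               3.335 * 10 + 1.34 * (1 / 0.25 + 1 / 1.2) * 0.5,
               tolerance = 1e-12)
  # cost diverges at low speed, and v = 0 is rejected outright
  expect_gt(bout_total_cost(cf, 10, 1e-8), 1e8)
  expect_error(bout_total_cost(cf, 10, 0), "diverges")
})

test_that("straight-bout optimum solves the implicit equation", {
  none <- steady_coefficients("none")
  v_max <- sqrt(none$a0 / none$a2)
  # degenerate a_change = 0: minimiser of cost per distance, for any D
  expect_equal(optimal_speed_straight(none, c(1, 10, 100)), rep(v_max, 3))
  cf <- modify_coefficients(none, list(a_change = 1.34))
  # approaches the steady optimum from below as D grows
  v <- optimal_speed_straight(cf, c(4, 10, 1e2, 1e6))
  expect_true(all(diff(v) > 0))
  expect_true(all(v < v_max))
  expect_equal(v[4], v_max, tolerance = 1e-3)
  # agrees with the dense-grid minimiser of the bout cost
  expect_equal(optimal_speed_straight(cf, 10), grid_opt_straight(cf, 10),
               tolerance = 1e-4)
  # the root satisfies the implicit relation itself
  eff <- efficiency_params()
  v10 <- optimal_speed_straight(cf, 10)
  expect_equal(cf$a_change * v10^3 * eff$k / (cf$a0 - cf$a2 * v10^2), 10,
               tolerance = 1e-6)
})

test_that("circle cost per distance and its closed-form optimum agree with brute force", {
  none <- steady_coefficients("none")
  cf <- modify_coefficients(none, list(a_turn = 1.11))
  expect_equal(circle_cost_per_distance(cf, 1, 1), 2.22 + 0 + 1.115 + 1.11)
  # no turning cost (or infinite radius): straight-line cost per distance
  v <- c(0.5, 1, 1.5)
  expect_equal(circle_cost_per_distance(none, v, 2), steady_rate(none, v) / v)
  expect_equal(circle_cost_per_distance(cf, v, Inf), steady_rate(cf, v) / v)
  expect_equal(optimal_speed_circle(cf, Inf), sqrt(cf$a0 / cf$a2))
  expect_equal(optimal_speed_circle(none, c(1, 3)),
               rep(sqrt(none$a0 / none$a2), 2))
  expect_equal(optimal_speed_circle(cf, 1), grid_opt_circle(cf, 1, step = 1e-6),
               tolerance = 1e-6)
  expect_error(circle_cost_per_distance(cf, 0, 1), "> 0")
})

test_that("near-optimal band brackets the optimum at the requested cost excess", {
  cf <- reference_coefficients("none")
  curve <- function(u) circle_cost_per_distance(cf, u, 1)
  v_opt <- optimal_speed_circle(cf, 1)
  b <- near_optimal_band(curve, v_opt)
  expect_true(b$v_lo <= v_opt && v_opt <= b$v_hi)
  expect_equal(curve(b$v_lo), 1.01 * curve(v_opt), tolerance = 1e-6)
  expect_equal(curve(b$v_hi), 1.01 * curve(v_opt), tolerance = 1e-6)
  # dense-grid scan for the 1.01 * min crossings
  vv <- seq(1e-4, 3, by = 1e-5)
  cc <- curve(vv)
  thr <- 1.01 * curve(v_opt)
  expect_equal(b$v_lo, min(vv[cc <= thr]), tolerance = 1e-4)
  expect_equal(b$v_hi, max(vv[cc <= thr]), tolerance = 1e-4)
  # zero excess collapses the band; flat curves give an open band
  b0 <- near_optimal_band(curve, v_opt, fraction = 0)
  expect_identical(c(b0$v_lo, b0$v_hi), c(v_opt, v_opt))
  flat <- near_optimal_band(function(u) 1, 1)
  expect_identical(flat$v_hi, Inf)
  expect_identical(flat$v_lo, 0)
})

test_that("optima ignore a1, are scale invariant and monotone in D and R", {
  cf <- reference_coefficients("below_knee")
  D <- c(4, 6, 8, 10, 23); R <- c(1, 2, 3)
  for (da1 in c(-10, 10)) {
    cf2 <- modify_coefficients(cf, list(a1 = cf$a1 + da1))
    expect_equal(optimal_speed_straight(cf2, D), optimal_speed_straight(cf, D),
                 tolerance = 1e-9)
    expect_equal(optimal_speed_circle(cf2, R), optimal_speed_circle(cf, R))
  }
  for (c_scale in c(0.1, 3.7)) {
    cfs <- modify_coefficients(cf, lapply(
      cf[c("a0", "a1", "a2", "a_change", "a_turn")], function(a) a * c_scale))
    expect_equal(optimal_speed_straight(cfs, D), optimal_speed_straight(cf, D),
                 tolerance = 1e-9)
    expect_equal(optimal_speed_circle(cfs, R), optimal_speed_circle(cf, R))
  }
  expect_true(all(diff(optimal_speed_straight(cf, D)) > 0))
  expect_true(all(diff(optimal_speed_circle(cf, R)) > 0))
  v_max <- sqrt(cf$a0 / cf$a2)
  expect_true(all(optimal_speed_straight(cf, D) < v_max))
  expect_true(all(optimal_speed_circle(cf, R) < v_max))
})

test_that("root-solved and closed-form optima match grid minimisation on random coefficients", {
  set.seed(402)
  for (i in 1:20) {
    cf <- cost_coefficients(a0 = runif(1, 1, 6), a1 = runif(1, -3, 3),
                            a2 = runif(1, 0.5, 6),
                            a_change = runif(1, 0, 5),
                            a_turn = runif(1, 0, 10))
    D <- runif(1, 3, 25); R <- runif(1, 0.5, 4)
    expect_equal(optimal_speed_straight(cf, D), grid_opt_straight(cf, D),
                 tolerance = 1e-4)
    expect_equal(optimal_speed_circle(cf, R), grid_opt_circle(cf, R),
                 tolerance = 1e-4)
  }
})
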