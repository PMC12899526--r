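test_that("initialization is at energy equilibrium and closes the mass balance", {
  ind <- reference_individual("male", age = 40, height = 1.75, weight = 85)
  st <- initialize_balance(ind)
  expect_gt(st$fat, 0)
  expect_gt(st$lean, 0)
  expect_equal(st$fat + st$lean, 85)
  expect_equal(hall_weight(st), 85)
  tr <- simulate_weight(st, 0, horizon = 10, step = 1 / 52)
  expect_lt(max(abs(tr$weight - 85)), 0.1)
  # heavier individual, all else equal, carries more fat
  st2 <- initialize_balance(reference_individual("male", 40, 1.75, 95))
  expect_gt(st2$fat, st$fat)
  expect_error(initialize_balance(reference_individual("male", 40, 1.75, 30)),
               "nonphysical")
  expect_error(reference_individual("male", height = 1.0))
})

test_that("sustained intake changes settle near the 100 kJ/day-per-kg rule", {
  st <- initialize_balance(reference_individual())
  expect_equal(equilibrium_weight_change(-100), -1)
  expect_equal(equilibrium_weight_change(0), 0)
  expect_equal(equilibrium_weight_change(-200), -2)
  # full model agrees with the reduced-form equilibrium within 15%
  finals <- vapply(c(-500, -250, -100, 100, 300, 500), function(dei) {
    tr <- simulate_weight(st, dei, horizon = 40, step = 1 / 52,
                          out_times = c(0, 40))
    trajectory_summary(tr)$delta_final
  }, numeric(1))
  expected <- equilibrium_weight_change(c(-500, -250, -100, 100, 300, 500))
  expect_true(all(abs(finals - expected) <= 0.15 * abs(expected)))
  # asymptotic change is monotone in the intake change
  expect_true(all(diff(finals) > 0))
})

test_that("trajectory is monotone and matches the exponential reduced form", {
  st <- initialize_balance(reference_individual())
  times <- seq(0, 10, by = 0.25)
  tr <- simulate_weight(st, -100, horizon = 10, step = 1 / 52, out_times = times)
  dw <- tr$weight - tr$weight[1]
  expect_true(all(diff(dw) <= 1e-9))  # monotone approach to the asymptote
  red <- reduced_weight_trajectory(-100, times, tau = 1)
  # pointwise agreement within 20% of the asymptote after the first weeks
  keep <- times >= 0.25
  expect_true(all(abs(dw[keep] - red$delta_weight[keep]) <= 0.2))
  expect_equal(tr$bmi, tr$weight / 1.75^2)
})

test_that("integration settings are validated", {
  st <- initialize_balance(reference_individual())
  expect_error(simulate_weight(st, -100, step = 1 / 12), "1/52")
  expect_error(simulate_weight(st, NA), "finite")
})

test_that("fixed-step integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  st <- initialize_balance(reference_individual())
  tr <- simulate_weight(st, -300, horizon = 10, step = 1 / 52,
                        out_times = c(0, 1, 5, 10))
  fast <- ssbtax:::.hall_fast(st, -300)
  rhs <- function(t, y, parms) {
    list(ssbtax:::.hall_deriv(y, st, -300, fast$mass))
  }
  sol <- deSolve::lsoda(c(st$fat, st$lean, st$at),
                        times = c(0, 1, 5, 10) * 365, func = rhs,
                        rtol = 1e-10, atol = 1e-10)
  w_ref <- sol[, 2] + sol[, 3] + fast$mass
  w_ref[1] <- sol[1, 2] + sol[1, 3]  # baseline before the fast shift
  expect_equal(tr$weight, unname(w_ref), tolerance = 1e-6)
})

test_that("stratum weight response scales with the energy change", {
  ec <- tibble::tibble(sex = c("male", "male"), age_group = c("30-34", "30-34"),
                       income = c("total", "upper"),
                       delta_kcal_day = c(-20, -40))
  bmi <- tibble::tibble(sex = "male", age_group = "30-34",
                        income = c("total", "upper"),
                        mean_bmi = 26, sd_bmi = 4, mean_height_m = 1.73)
  wr <- stratum_weight_response(ec, bmi, years = 1:3, horizon = 30)
  expect_equal(nrow(wr), 2)
  # near-linear in the intake change at these magnitudes
  expect_equal(wr$delta_weight_eq[2] / wr$delta_weight_eq[1], 2, tolerance = 0.02)
  expect_true(all(wr$delta_weight_eq < 0))
  expect_true(all(abs(wr$delta_weight_y1) < abs(wr$delta_weight_eq)))
})
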