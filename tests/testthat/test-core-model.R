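test_that("heat coefficients reproduce hand-evaluated linear parts", {
  s <- subject_v4()
  lvl <- load_parameter_set("level")
  # independent hand arithmetic:
  # am: 4.49 + 1.35e-2*90.58 - 4.87e-2*34 - 1.39*1.72 = 1.66623
  # sl: -1.46 - 1.44e-2*90.58 + 3.55e-3*34 + 1.75*1.72 = 0.366348
  m <- linear_coefficient_margins(s, lvl)
  expect_equal(unname(m["am"]), 1.66623, tolerance = 1e-5)
  expect_equal(unname(m["sl"]), 0.366348, tolerance = 1e-5)

  # with w4 = 0 the coefficients equal the linear parts exactly
  w <- lvl$w; w[c("w4am", "w4sl")] <- 0
  h <- compute_heat_coefficients(s, parameter_set(w), normative_torques())
  expect_equal(h$h_am, rep(unname(m["am"]), 6))
  expect_equal(h$h_sl, rep(unname(m["sl"]), 6))
})

test_that("all-zero weights give all-zero heat coefficients", {
  h <- compute_heat_coefficients(subject_v4(), parameter_set(rep(0, 10)),
                                 normative_torques())
  expect_equal(h$h_am, rep(0, 6))
  expect_equal(h$h_sl, rep(0, 6))
})

test_that("internal work rate matches trivial and brute-force cases", {
  # no motion, no work
  tr <- gait_trial("a", 1.3, 0, matrix(rnorm(12), 6), matrix(0, 6, 2))
  expect_equal(internal_work_rate(tr), c(0, 0), ignore_attr = TRUE)

  # single-term product: 10 N·m * 2 rad/s = 20 W
  tau <- matrix(c(10, 0, 0, 0, 0, 0), 6, 1)
  qd <- matrix(c(2, 0, 0, 0, 0, 0), 6, 1)
  expect_equal(internal_work_rate(gait_trial("a", 1, 0, tau, qd)), 20,
               ignore_attr = TRUE)

  withr::with_seed(5, {
    tr <- random_trial()
    expect_equal(internal_work_rate(tr),
                 loop_work_rate(tr$torques, tr$velocities),
                 ignore_attr = TRUE, tolerance = 1e-12)
  })
})

test_that("heat rate matches trivial cases and is sign-symmetric", {
  h0 <- structure(list(h_am = rep(0, 6), h_sl = rep(0, 6)),
                  class = "heat_coefficients")
  withr::with_seed(6, tr <- random_trial())
  expect_equal(heat_rate(tr, h0), rep(0, 100), ignore_attr = TRUE)

  # single sample: 0.5*|10| + 0.1*|10*2| = 7 W
  tau <- matrix(c(10, 0, 0, 0, 0, 0), 6, 1)
  qd <- matrix(c(2, 0, 0, 0, 0, 0), 6, 1)
  h <- structure(list(h_am = c(0.5, rep(0, 5)), h_sl = c(0.1, rep(0, 5))),
                 class = "heat_coefficients")
  expect_equal(heat_rate(gait_trial("a", 1, 0, tau, qd), h), 7,
               ignore_attr = TRUE)

  # flipping the sign of all torques and velocities leaves heat unchanged
  h2 <- structure(list(h_am = runif(6), h_sl = runif(6)),
                  class = "heat_coefficients")
  flipped <- gait_trial(tr$subject_id, tr$speed, tr$grade,
                        -tr$torques, -tr$velocities)
  expect_equal(heat_rate(tr, h2), heat_rate(flipped, h2))
})

test_that("basal rate follows the sex-specific closed forms", {
  # male, M=90.58, A=34, H=1.72 -> 1942.8 kcal/day -> 94.08 W
  expect_equal(basal_rate(subject_v4()), 94.08, tolerance = 1e-4)

  # linearity in mass: difference = 13.75 * dM kcal/day
  s1 <- subject_profile("a", 70, 1.75, 30, "male")
  s2 <- subject_profile("b", 80, 1.75, 30, "male")
  expect_equal(basal_rate(s2) - basal_rate(s1), 13.75 * 10 * 4184 / 86400)

  # female equation differs from male for identical anthropometrics
  sf <- subject_profile("c", 70, 1.75, 30, "female")
  expect_equal(basal_rate(sf),
               (655.1 + 9.563 * 70 + 1.850 * 175 - 4.676 * 30) * 4184 / 86400)
})

test_that("metabolic rate series assembles its components", {
  withr::with_seed(7, tr <- random_trial())
  s <- subject_v4()
  norms <- normative_torques()

  # zero weights, no basal: rate collapses to the work rate
  zero <- parameter_set(rep(0, 10))
  bd <- metabolic_rate_series(tr, s, zero, norms, include_basal = FALSE)
  expect_equal(bd$rate_series, bd$work_rate_series)
  expect_equal(bd$heat_rate_series, rep(0, 100), ignore_attr = TRUE)

  # zero torques with basal on: constant series at the basal rate
  quiet <- gait_trial("4", 1.3, 0, matrix(0, 6, 100),
                      matrix(rnorm(600), 6))
  bdq <- metabolic_rate_series(quiet, s, simple_params(), norms)
  expect_equal(bdq$rate_series, rep(basal_rate(s), 100), ignore_attr = TRUE)

  # mean rate equals a per-sample brute-force recomputation
  p <- simple_params()
  bd2 <- metabolic_rate_series(tr, s, p, norms)
  h <- compute_heat_coefficients(s, p, norms)
  manual <- loop_work_rate(tr$torques, tr$velocities) +
    loop_heat_rate(tr$torques, tr$velocities, h$h_am, h$h_sl) + basal_rate(s)
  expect_equal(bd2$mean_rate, sum(manual) / 100, tolerance = 1e-12)
})

test_that("per-distance cost is rate over mass over speed", {
  s <- subject_profile("x", 90, 1.80, 30, "male")
  expect_equal(metabolic_cost(468, s, 1.3), 4)
  expect_equal(metabolic_cost(468, s, 2.6), 2)  # doubling speed halves cost
  expect_equal(metabolic_cost(0, s, 1.3), 0)
  expect_error(metabolic_cost(468, s, 0), "speed")
})

test_that("torque scaling is covariant and units round-trip", {
  withr::with_seed(8, tr <- random_trial())
  s <- subject_v4()
  norms <- normative_torques()
  p <- simple_params()
  k <- 3.7
  scaled <- gait_trial(tr$subject_id, tr$speed, tr$grade,
                       k * tr$torques, tr$velocities)
  expect_equal(internal_work_rate(scaled), k * internal_work_rate(tr))
  h <- compute_heat_coefficients(s, p, norms)
  expect_equal(heat_rate(scaled, h), k * heat_rate(tr, h))

  bd <- metabolic_rate_series(tr, s, p, norms)
  expect_equal(bd$cost_per_kg_per_m * tr$speed * s$mass, bd$mean_rate)
})
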