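test_that("objective is the mean squared cost residual", {
  withr::with_seed(21, {
    st <- generate_study(cohort_spec(n_subjects = 4),
                         wspec = waveform_spec(noise_sd = 0.05), seed = 3)
    grades <- vapply(st$trials, `[[`, 0, "grade")
    ts <- training_set(st$trials[grades == 0], st$subjects)
    p <- simple_params()
    norms <- normative_torques()

    # hand-rolled residual loop
    acc <- 0
    for (j in seq_along(ts$trials)) {
      tr <- ts$trials[[j]]
      s <- ts$subjects[[tr$subject_id]]
      em <- metabolic_rate_series(tr, s, p, norms)$cost_per_kg_per_m
      acc <- acc + (ts$measured_cost[j] - em)^2
    }
    expect_equal(mee_objective(p, ts, norms), acc / ts$n_trials,
                 tolerance = 1e-12)

    # a perfect fit scores zero: use the model's own costs as "measured"
    em <- predict_costs(p, ts, norms)
    perfect <- training_set(ts$trials, ts$subjects, measured_cost = em)
    expect_equal(mee_objective(p, perfect, norms), 0)

    # single trial: objective is the squared residual
    one <- training_set(ts$trials[1], ts$subjects,
                        measured_cost = em[1] + 0.3)
    expect_equal(mee_objective(p, one, norms), 0.09, tolerance = 1e-10)
  })
})

test_that("linear and multiplier constraint margins match the closed forms", {
  s <- subject_v4()
  norms <- normative_torques()

  zero <- parameter_set(rep(0, 10))
  expect_equal(unname(linear_coefficient_margins(s, zero)), c(0, 0))
  mm <- multiplier_margins(s, zero, norms)
  expect_equal(mm$am, rep(1, 6))
  expect_equal(mm$sl, rep(1, 6))

  neg <- parameter_set(c(w0am = -1, w1am = 0, w2am = 0, w3am = 0, w4am = 0,
                         w0sl = 0, w1sl = 0, w2sl = 0, w3sl = 0, w4sl = 0))
  expect_equal(unname(linear_coefficient_margins(s, neg)["am"]), -1)

  # boundary construction: w4am = -1/(ratio * tau_i) makes the margin 0
  ratio <- s$tau_knee_max / norms$tau_knee_avg_max
  w <- rep(0, 10); names(w) <- names(zero$w)
  w["w4am"] <- -1 / (ratio * norms$tau_i_avg_max[1])
  mm <- multiplier_margins(s, parameter_set(w), norms)
  expect_equal(mm$am, rep(0, 6), tolerance = 1e-12)

  # randomized inputs match direct formula evaluation
  withr::with_seed(31, {
    for (rep in 1:20) {
      w <- rnorm(10); names(w) <- names(zero$w)
      p <- parameter_set(w)
      lm_ <- linear_coefficient_margins(s, p)
      expect_equal(unname(lm_["am"]),
                   w["w0am"] + w["w1am"] * s$mass + w["w2am"] * s$age +
                     w["w3am"] * s$height, ignore_attr = TRUE)
      mm <- multiplier_margins(s, p, norms)
      expect_equal(mm$sl, 1 + w[["w4sl"]] * ratio * norms$tau_i_avg_max)
    }
  })
})

test_that("no-recharge margin equals the brute-force minimum", {
  withr::with_seed(32, {
    tr <- random_trial()
    h <- structure(list(h_am = runif(6), h_sl = runif(6)),
                   class = "heat_coefficients")
    expect_equal(no_recharge_margin(tr, h),
                 loop_no_recharge(tr$torques, tr$velocities, h$h_am, h$h_sl))

    # zero torques: margin exactly 0
    quiet <- gait_trial("a", 1, 0, matrix(0, 6, 50), matrix(rnorm(300), 6))
    expect_equal(no_recharge_margin(quiet, h), 0)

    # h_sl >= 1 and h_am >= 0 guarantee feasibility (|x| >= -x)
    h1 <- structure(list(h_am = runif(6), h_sl = 1 + runif(6)),
                    class = "heat_coefficients")
    for (rep in 1:10) expect_gte(no_recharge_margin(random_trial(), h1), 0)
  })
})

test_that("cost bound margins behave at and beyond the cap", {
  m <- emax_margins(model_cost = c(4, 4.8), measured_cost = c(4, 4),
                    fraction = 1.10)
  expect_equal(m$lower, c(4, 4.8))
  expect_equal(m$upper, c(0.4, -0.4))
  expect_equal(emax_margins(0, 5, 1.1)$lower, 0)  # boundary-feasible

  pol <- emax_policy()
  expect_equal(emax_fraction(pol, "downhill", 1.3), 1.15)
  expect_equal(emax_fraction(pol, "downhill", 0.8), 1.10)
  expect_error(emax_fraction(pol, "level", 2.5), "no upper-bound fraction")
})

test_that("calibration is deterministic, monotone across stages, and verifiable", {
  withr::with_seed(41, {
    st <- generate_study(cohort_spec(n_subjects = 6),
                         wspec = waveform_spec(noise_sd = 0.03), seed = 5)
  })
  grades <- vapply(st$trials, `[[`, 0, "grade")
  ts <- training_set(st$trials[grades == 0], st$subjects)
  norms <- normative_torques()
  pol <- emax_policy()

  r1 <- calibrate(ts, norms, pol, small_calib(seed = 2))
  r2 <- calibrate(ts, norms, pol, small_calib(seed = 2))
  expect_identical(r1$params$w, r2$params$w)
  expect_identical(r1$objective_value, r2$objective_value)

  # refinement never increases the staged (penalized) objective
  expect_lte(r1$stage_trace[["after_refinement"]],
             r1$stage_trace[["after_swarm"]])

  # the refined objective is no worse than at the generating parameters
  expect_lte(r1$objective_value,
             mee_objective(st$true_params, ts, norms))

  # feasibility closure: a feasible flag re-verifies every margin
  if (r1$feasible) {
    p <- r1$params
    em <- predict_costs(p, ts, norms)
    for (id in names(ts$subjects)) {
      s <- ts$subjects[[id]]
      expect_true(all(linear_coefficient_margins(s, p) >= -1e-8))
      expect_true(all(unlist(multiplier_margins(s, p, norms)) >= -1e-8))
    }
    for (j in seq_along(ts$trials)) {
      tr <- ts$trials[[j]]
      h <- compute_heat_coefficients(ts$subjects[[tr$subject_id]], p, norms)
      expect_gte(no_recharge_margin(tr, h), -1e-8)
      frac <- emax_fraction(pol, ts$condition, tr$speed)
      expect_gte(em[j], -1e-8)
      expect_gte(frac * ts$measured_cost[j] - em[j], -1e-8)
    }
  }

  # penalty consistency: at a feasible point the penalized and plain
  # objectives coincide
  design <- jointmee:::build_design(ts, norms, pol, TRUE)
  wfeas <- synthetic_truth_params()$w
  expect_equal(jointmee:::penalized_objective(wfeas, design, 1e5),
               mee_objective(synthetic_truth_params(), ts, norms),
               tolerance = 1e-12)
})
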