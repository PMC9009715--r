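test_that("cohort generation is deterministic and follows its spec", {
  spec <- cohort_spec(seed = 42)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 12)
  sexes <- vapply(c1, `[[`, "", "sex")
  expect_equal(sum(sexes == "male"), 6)
  # leading 8-subject subset stays sex-balanced (alternating draw)
  expect_equal(sum(sexes[1:8] == "male"), 4)
  # imputed knee torques by sex
  taus <- vapply(c1, `[[`, 0, "tau_knee_max")
  expect_true(all(taus[sexes == "male"] == 212.4))
  expect_true(all(taus[sexes == "female"] == 107.6))
})

test_that("a zero-variance cohort collapses to the stratum means", {
  spec <- cohort_spec(n_subjects = 4,
                      male = list(mass = c(75, 0), height = c(1.8, 0),
                                  age = c(25, 0)),
                      female = list(mass = c(64, 0), height = c(1.68, 0),
                                    age = c(22, 0)), seed = 1)
  cc <- generate_cohort(spec)
  masses <- vapply(cc, `[[`, 0, "mass")
  expect_equal(unname(masses), c(75, 64, 75, 64))
})

test_that("large-cohort sample means sit within 3 SE of the stratum means", {
  spec <- cohort_spec(n_subjects = 1000, male_fraction = 1, seed = 9)
  cc <- generate_cohort(spec)
  masses <- vapply(cc, `[[`, 0, "mass")
  se <- 14.73 / sqrt(1000)
  expect_lt(abs(mean(masses) - 74.72), 3 * se)
})

test_that("trial generation is seeded, grade-monotone and shape-correct", {
  s <- subject_profile("a", 75, 1.8, 30, "male")
  t1 <- generate_trial(s, 1.3, 0, seed = 7)
  t2 <- generate_trial(s, 1.3, 0, seed = 7)
  expect_identical(t1, t2)
  expect_equal(dim(t1$torques), c(6, 100))
  expect_true(all(is.finite(t1$torques)))

  up <- generate_trial(s, 1.3, 8, seed = 7)
  down <- generate_trial(s, 1.3, -8, seed = 7)
  expect_gt(mean(abs(up$torques)), mean(abs(t1$torques)))
  expect_gt(mean(abs(t1$torques)), mean(abs(down$torques)))

  flat <- generate_trial(s, 1.3, 0,
                         waveform_spec(torque_amp = rep(0, 6),
                                       velocity_amp = rep(0, 6)), seed = 1)
  expect_true(all(flat$torques == 0) && all(flat$velocities == 0))
})

test_that("measured-cost generation is exact without noise and calibrated with it", {
  s <- subject_profile("a", 75, 1.8, 30, "male")
  tr <- generate_trial(s, 1.3, 0, seed = 3)
  p <- synthetic_truth_params()
  norms <- normative_torques()

  exact <- generate_measured_cost(tr, s, p, norms, noise_sd = 0)
  expect_equal(exact,
               metabolic_rate_series(tr, s, p, norms)$cost_per_kg_per_m)

  # reproducible under seed
  c1 <- generate_measured_cost(tr, s, p, norms, noise_sd = 0.05, seed = 11)
  c2 <- generate_measured_cost(tr, s, p, norms, noise_sd = 0.05, seed = 11)
  expect_identical(c1, c2)

  # Monte-Carlo: empirical CV within 3 SE of the nominal noise level
  withr::with_seed(12, {
    reps <- vapply(1:1000, function(i)
      generate_measured_cost(tr, s, p, norms, noise_sd = 0.02, seed = NULL), 0)
  })
  cv <- sd(reps) / mean(reps)
  se_cv <- 0.02 / sqrt(2 * 999)
  expect_lt(abs(cv - 0.02), 3 * se_cv)

  # infeasible ground truth is refused
  bad <- parameter_set(c(w0am = -5, w1am = 0, w2am = 0, w3am = 0, w4am = 0,
                         w0sl = 1, w1sl = 0, w2sl = 0, w3sl = 0, w4sl = 0))
  expect_error(generate_measured_cost(tr, s, bad, norms, 0), "infeasible")
})

test_that("full studies are deterministic and internally consistent", {
  st1 <- generate_study(cohort_spec(n_subjects = 4), seed = 5)
  st2 <- generate_study(cohort_spec(n_subjects = 4), seed = 5)
  expect_identical(st1$measured_cost, st2$measured_cost)
  expect_length(st1$trials, 4 * 6)
  # the stored measured rate is cost times speed
  for (j in seq_along(st1$trials)) {
    tr <- st1$trials[[j]]
    expect_equal(tr$measured_rate, st1$measured_cost[j] * tr$speed)
  }
})
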