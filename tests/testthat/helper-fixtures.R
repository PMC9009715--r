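# Shared fixtures and independent brute-force oracles. The oracles use
# explicit per-(dof, sample) loops on purpose: they check the vectorized
# implementations against the plainest possible arithmetic.

subject_v4 <- function() subject_profile("4", 90.58, 1.72, 34, "male")

random_trial <- function(subject_id = "S01", speed = 1.3, grade = 0,
                         n_dof = 6, n_samples = 100) {
  gait_trial(subject_id, speed, grade,
             torques = matrix(rnorm(n_dof * n_samples, sd = 40), n_dof),
             velocities = matrix(rnorm(n_dof * n_samples, sd = 2), n_dof))
}

loop_work_rate <- function(torques, velocities) {
  n_dof <- nrow(torques); n <- ncol(torques)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n_dof)) acc <- acc + torques[i, t] * velocities[i, t]
    out[t] <- acc
  }
  out
}

loop_heat_rate <- function(torques, velocities, h_am, h_sl) {
  n_dof <- nrow(torques); n <- ncol(torques)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n_dof)) {
      acc <- acc + h_am[i] * abs(torques[i, t]) +
        h_sl[i] * abs(torques[i, t] * velocities[i, t])
    }
    out[t] <- acc
  }
  out
}

loop_no_recharge <- function(torques, velocities, h_am, h_sl) {
  worst <- Inf
  for (i in seq_len(nrow(torques))) {
    for (t in seq_len(ncol(torques))) {
      p <- torques[i, t] * velocities[i, t]
      m <- p + h_am[i] * abs(torques[i, t]) + h_sl[i] * abs(p)
      if (m < worst) worst <- m
    }
  }
  unname(worst)
}

# a small feasible parameter set for handmade trials
simple_params <- function() {
  parameter_set(c(w0am = 0.8, w1am = 0, w2am = 0, w3am = 0, w4am = 0,
                  w0sl = 1.1, w1sl = 0, w2sl = 0, w3sl = 0, w4sl = 0))
}

# cheap calibration settings for unit tests (the acceptance test uses the
# defaults); the variable-projection stage carries most of the optimization
small_calib <- function(seed = 1) {
  calibration_config(swarm_size = 20, max_iters = 30, stall_iters = 10,
                     seed = seed)
}

# one small synthetic training/validation pair at a given grade
small_split <- function(study, grade) {
  grades <- vapply(study$trials, `[[`, 0, "grade")
  train_ids <- names(study$subjects)[seq_len(round(2 / 3 * length(study$subjects)))]
  in_train <- vapply(study$trials,
                     function(t) t$subject_id %in% train_ids, TRUE)
  list(train = training_set(study$trials[grades == grade & in_train],
                            study$subjects),
       valid = training_set(study$trials[grades == grade & !in_train],
                            study$subjects))
}
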