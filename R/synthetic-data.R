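# Evaluate code under a fixed seed without touching the caller's RNG stream,
# or under the current stream when seed is NULL (used when an outer call
# already fixed the seed).
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Cohort specification
#'
#' Sex-stratified anthropometric distributions (mean +/- sample SD) from
#' which synthetic subjects are drawn. The defaults reproduce the training
#' strata of the reference walking study: males 74.72 +/- 14.73 kg,
#' 1.80 +/- 0.08 m, 25.00 +/- 5.94 yr; females 64.30 +/- 9.32 kg,
#' 1.68 +/- 0.08 m, 22.25 +/- 3.95 yr; 12 subjects, half of each sex.
#'
#' @param n_subjects Cohort size.
#' @param male_fraction Fraction of male subjects.
#' @param male,female Named lists with `mass`, `height`, `age`, each
#'   `c(mean, sd)`.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, male_fraction = 0.5,
                        male = list(mass = c(74.72, 14.73),
                                    height = c(1.80, 0.08),
                                    age = c(25.00, 5.94)),
                        female = list(mass = c(64.30, 9.32),
                                      height = c(1.68, 0.08),
                                      age = c(22.25, 3.95)),
                        seed = 0) {
  structure(list(n_subjects = n_subjects, male_fraction = male_fraction,
                 male = male, female = female, seed = seed),
            class = "cohort_spec")
}

# normal draw truncated to positive support (resampled)
rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic cohort
#'
#' Draws subjects from the sex-specific truncated normal distributions of a
#' [cohort_spec()]. Sexes alternate male/female until one stratum is
#' exhausted, so any leading subset of an even split stays sex-balanced.
#' Maximum knee torque is imputed by sex.
#'
#' @param spec A [cohort_spec()].
#' @return Named list of [subject_profile()] objects.
#' @export
generate_cohort <- function(spec) {
  n <- spec$n_subjects
  n_male <- round(spec$male_fraction * n)
  sexes <- character(n)
  m_left <- n_male; f_left <- n - n_male
  for (k in seq_len(n)) {
    take_male <- if (m_left > 0 && f_left > 0) k %% 2 == 1 else m_left > 0
    sexes[k] <- if (take_male) "male" else "female"
    if (take_male) m_left <- m_left - 1 else f_left <- f_left - 1
  }
  with_seed_opt(spec$seed, {
    subjects <- lapply(seq_len(n), function(k) {
      d <- if (sexes[k] == "male") spec$male else spec$female
      subject_profile(
        subject_id = sprintf("S%02d", k),
        mass = rnorm_pos(1, d$mass[1], d$mass[2]),
        height = rnorm_pos(1, d$height[1], d$height[2]),
        age = rnorm_pos(1, d$age[1], d$age[2]),
        sex = sexes[k]
      )
    })
    stats::setNames(subjects, vapply(subjects, `[[`, "", "subject_id"))
  })
}

#' Waveform specification for synthetic gait cycles
#'
#' Amplitude and shape parameters for the random truncated Fourier series
#' that stand in for joint moment and angular velocity waveforms. These are
#' statistical stand-ins with the scale and shape of averaged gait data, not
#' biomechanically realistic curves. Torque amplitudes are per unit body
#' mass (N·m·kg^-1) and scale with grade through
#' `exp(grade_gain * grade)`, so uphill trials have larger extensor torques
#' than level than downhill (and the scale stays positive at any grade);
#' velocity amplitudes (rad·s^-1, referenced to 1.3 m·s^-1) scale
#' proportionally with speed. The defaults put the generated per-distance
#' costs in the range indirect calorimetry reports for treadmill walking at
#' these speeds and grades (roughly 3.5-7 J·kg^-1·m^-1 from downhill to
#' uphill).
#'
#' @param n_dof Degrees of freedom (6: hip, knee, ankle, bilaterally).
#' @param n_samples Samples per gait cycle (100).
#' @param torque_amp Per-DOF peak torque per body mass, N·m·kg^-1.
#' @param velocity_amp Per-DOF peak angular velocity at 1.3 m·s^-1, rad·s^-1.
#' @param harmonics Number of Fourier harmonics.
#' @param grade_gain Log torque-amplitude change per percent grade.
#' @param noise_sd Multiplicative noise SD on generated measured costs.
#' @return Object of class `waveform_spec`.
#' @export
waveform_spec <- function(n_dof = 6, n_samples = 100,
                          torque_amp = rep(c(0.5, 0.4, 0.6), 2),
                          velocity_amp = rep(c(2.5, 5.0, 3.5), 2),
                          harmonics = 3, grade_gain = 0.065,
                          noise_sd = 0.05) {
  stopifnot(length(torque_amp) == n_dof, length(velocity_amp) == n_dof,
            all(torque_amp >= 0), all(velocity_amp >= 0), grade_gain >= 0)
  structure(list(n_dof = n_dof, n_samples = n_samples,
                 torque_amp = torque_amp, velocity_amp = velocity_amp,
                 harmonics = harmonics, grade_gain = grade_gain,
                 noise_sd = noise_sd),
            class = "waveform_spec")
}

# one random periodic waveform: truncated Fourier series with 1/k-decaying
# random coefficients, rescaled to unit peak (zero when all coefficients
# vanish numerically)
fourier_wave <- function(n_samples, harmonics) {
  t <- seq(0, 1, length.out = n_samples + 1)[seq_len(n_samples)]
  s <- numeric(n_samples)
  for (k in seq_len(harmonics)) {
    s <- s + stats::rnorm(1, 0, 1 / k) * cos(2 * pi * k * t) +
      stats::rnorm(1, 0, 1 / k) * sin(2 * pi * k * t)
  }
  peak <- max(abs(s))
  if (peak > 0) s / peak else s
}

#' Generate a synthetic gait trial
#'
#' Builds each DOF's torque and velocity waveform as an independent random
#' truncated Fourier series over one gait cycle, with torque amplitudes
#' proportional to body mass and increased (decreased) on uphill (downhill)
#' grades, and velocity amplitudes proportional to speed.
#'
#' @param subject A [subject_profile()].
#' @param speed Walking speed, m·s^-1.
#' @param grade Grade in percent.
#' @param spec A [waveform_spec()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A [gait_trial()] (without a measured rate).
#' @export
generate_trial <- function(subject, speed, grade, spec = waveform_spec(),
                           seed = NULL) {
  gscale <- exp(spec$grade_gain * grade)
  vscale <- speed / 1.3
  with_seed_opt(seed, {
    torques <- matrix(0, spec$n_dof, spec$n_samples)
    velocities <- matrix(0, spec$n_dof, spec$n_samples)
    for (i in seq_len(spec$n_dof)) {
      torques[i, ] <- subject$mass * spec$torque_amp[i] * gscale *
        fourier_wave(spec$n_samples, spec$harmonics)
      velocities[i, ] <- spec$velocity_amp[i] * vscale *
        fourier_wave(spec$n_samples, spec$harmonics)
    }
    gait_trial(subject$subject_id, speed, grade, torques, velocities)
  })
}

#' Ground-truth weighting parameters for synthetic studies
#'
#' A documented, feasible-by-construction parameter set used to generate
#' synthetic "measured" costs: across plausible adult anthropometrics both
#' linear coefficient parts stay positive, the power-family coefficient
#' stays near or above 1 (which makes the no-recharge condition hold for
#' any waveform), and the `w4` multipliers stay well inside feasibility.
#'
#' @return A [parameter_set()] labelled `"synthetic-truth"`.
#' @export
synthetic_truth_params <- function() {
  parameter_set(c(w0am = 1.2, w1am = 8e-3, w2am = -1e-2, w3am = -0.3,
                  w4am = -5e-4,
                  w0sl = 0.55, w1sl = 4e-3, w2sl = 1.5e-3, w3sl = 0.12,
                  w4sl = 5e-4),
                label = "synthetic-truth")
}

# Eq-style feasibility of a parameter set for one subject and trial
params_feasible_for <- function(trial, subject, params, norms, tol = 1e-10) {
  lin <- linear_coefficient_margins(subject, params)
  mm <- multiplier_margins(subject, params, norms)
  h <- compute_heat_coefficients(subject, params, norms)
  min(lin, unlist(mm), no_recharge_margin(trial, h)) >= -tol
}

#' Generate a noisy measured metabolic cost
#'
#' Evaluates the joint-space model at a known ground-truth parameter set and
#' perturbs the per-distance cost with multiplicative Gaussian noise
#' (truncated so the result stays positive). Refuses to generate from a
#' parameter set that is infeasible for the subject/trial, which would make
#' the fixture unlearnable under the calibration constraints.
#'
#' @param trial A [gait_trial()].
#' @param subject The matching [subject_profile()].
#' @param true_params Ground-truth [parameter_set()].
#' @param norms A [normative_torques()].
#' @param noise_sd Noise SD as a fraction of the cost.
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param include_basal Include the basal term (default `TRUE`).
#' @return Measured cost in J·kg^-1·m^-1.
#' @export
generate_measured_cost <- function(trial, subject, true_params,
                                   norms = normative_torques(),
                                   noise_sd = 0.05, seed = NULL,
                                   include_basal = TRUE) {
  if (!params_feasible_for(trial, subject, true_params, norms)) {
    stop("ground-truth parameters are infeasible for this subject/trial; ",
         "refusing to generate an unlearnable fixture", call. = FALSE)
  }
  cost <- metabolic_rate_series(trial, subject, true_params, norms,
                                include_basal)$cost_per_kg_per_m
  if (noise_sd == 0) return(cost)
  with_seed_opt(seed, {
    out <- cost * (1 + stats::rnorm(1, 0, noise_sd))
    while (out <= 0) out <- cost * (1 + stats::rnorm(1, 0, noise_sd))
    out
  })
}

#' Generate a complete synthetic walking study
#'
#' Draws a cohort, generates one trial per subject for every speed-grade
#' combination, and attaches measured metabolic rates derived from a
#' ground-truth parameter set plus multiplicative noise. The default layout
#' mirrors the reference protocol: 12 subjects, speeds 0.8 and 1.3 m·s^-1,
#' grades -8, 0 and +8 percent.
#'
#' @param cohort A [cohort_spec()].
#' @param speeds,grades Condition grids.
#' @param wspec A [waveform_spec()]; its `noise_sd` drives the measured-cost
#'   noise.
#' @param true_params Ground-truth [parameter_set()].
#' @param norms A [normative_torques()].
#' @param seed Master integer seed; fully determines the study.
#' @return Object of class `synthetic_study`: `subjects` (named list),
#'   `trials` (list of [gait_trial()] with `measured_rate` filled in),
#'   `measured_cost` (vector aligned with `trials`), `true_params`, `seed`.
#' @export
generate_study <- function(cohort = cohort_spec(), speeds = c(0.8, 1.3),
                           grades = c(-8, 0, 8), wspec = waveform_spec(),
                           true_params = synthetic_truth_params(),
                           norms = normative_torques(), seed = 0) {
  withr::with_seed(seed, {
    spec <- cohort
    spec$seed <- NULL  # absent seed reads as NULL: draw from the outer stream
    subjects <- generate_cohort(spec)
    trials <- list()
    costs <- numeric(0)
    for (id in names(subjects)) {
      for (g in grades) {
        for (v in speeds) {
          tr <- generate_trial(subjects[[id]], v, g, wspec, seed = NULL)
          cost <- generate_measured_cost(tr, subjects[[id]], true_params,
                                         norms, wspec$noise_sd, seed = NULL)
          tr$measured_rate <- cost * v
          trials[[length(trials) + 1]] <- tr
          costs <- c(costs, cost)
        }
      }
    }
    structure(list(subjects = subjects, trials = trials,
                   measured_cost = costs, true_params = true_params,
                   seed = seed),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects, %d trials, seed %d\n",
              length(x$subjects), length(x$trials), x$seed))
  invisible(x)
}
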