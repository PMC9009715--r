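#' Subject-specific heat coefficients
#'
#' Evaluates the two heat-coefficient families from the weighting parameters
#' and the subject's anthropometrics:
#' \deqn{h_i^{am} = (w_0^{am} + w_1^{am} M + w_2^{am} A + w_3^{am} H)
#'   \left(1 + w_4^{am} \frac{\tau_{knee}^{max}}{\tilde\tau_{knee}^{max}}
#'   \tilde\tau_i^{max}\right)}
#' and analogously for \eqn{h_i^{sl}} with the `sl` weights. `h_am` weights
#' the absolute joint torque (units W per N·m) and `h_sl` the absolute joint
#' power (dimensionless).
#'
#' Negative coefficients are returned as-is; deciding whether a parameter
#' set is admissible is the constraint checker's job, and clipping here
#' would mask infeasible sets.
#'
#' @param subject A [subject_profile()].
#' @param params A [parameter_set()].
#' @param norms A [normative_torques()].
#' @return An object of class `heat_coefficients`: list with numeric vectors
#'   `h_am` and `h_sl` of length `n_dof`.
#' @export
compute_heat_coefficients <- function(subject, params, norms) {
  w <- params$w
  if (!all(is.finite(w))) stop("non-finite weighting parameters", call. = FALSE)
  if (!all(norms$tau_i_avg_max > 0) || norms$tau_knee_avg_max <= 0) {
    stop("normative torques must be positive", call. = FALSE)
  }
  lin_am <- w[["w0am"]] + w[["w1am"]] * subject$mass +
    w[["w2am"]] * subject$age + w[["w3am"]] * subject$height
  lin_sl <- w[["w0sl"]] + w[["w1sl"]] * subject$mass +
    w[["w2sl"]] * subject$age + w[["w3sl"]] * subject$height
  ratio <- subject$tau_knee_max / norms$tau_knee_avg_max
  mult_am <- 1 + w[["w4am"]] * ratio * norms$tau_i_avg_max
  mult_sl <- 1 + w[["w4sl"]] * ratio * norms$tau_i_avg_max
  structure(list(h_am = lin_am * mult_am, h_sl = lin_sl * mult_sl),
            class = "heat_coefficients")
}

#' Internal mechanical work rate over the gait cycle
#'
#' Per-sample sum over degrees of freedom of joint torque times joint
#' angular velocity. May be negative (eccentric phases).
#'
#' @param trial A [gait_trial()].
#' @return Numeric vector of length `n_samples`, in W.
#' @export
internal_work_rate <- function(trial) {
  colSums(trial$torques * trial$velocities)
}

#' Heat liberation rate over the gait cycle
#'
#' Per-sample heat-exchange term: `sum_i h_am[i] |tau_i(t)| +
#' sum_i h_sl[i] |tau_i(t) qdot_i(t)|`. Non-negative whenever the
#' coefficients are non-negative.
#'
#' @param trial A [gait_trial()].
#' @param h A `heat_coefficients` object with vectors of length `n_dof`.
#' @return Numeric vector of length `n_samples`, in W.
#' @export
heat_rate <- function(trial, h) {
  n_dof <- nrow(trial$torques)
  if (length(h$h_am) != n_dof || length(h$h_sl) != n_dof) {
    stop("heat coefficient length does not match the trial's DOF count",
         call. = FALSE)
  }
  colSums(h$h_am * abs(trial$torques)) +
    colSums(h$h_sl * abs(trial$torques * trial$velocities))
}

# kcal/day -> W
KCAL_DAY_TO_W <- 4184 / 86400

#' Basal metabolic rate (Harris-Benedict)
#'
#' Sex-specific Harris-Benedict basal metabolic rate, converted from
#' kcal·day^-1 to watts. This is the non-muscular term of the metabolic
#' rate decomposition.
#'
#' @param subject A [subject_profile()].
#' @return Basal rate in W.
#' @export
basal_rate <- function(subject) {
  h_cm <- 100 * subject$height
  kcal_day <- if (subject$sex == "male") {
    66.5 + 13.75 * subject$mass + 5.003 * h_cm - 6.755 * subject$age
  } else {
    655.1 + 9.563 * subject$mass + 1.850 * h_cm - 4.676 * subject$age
  }
  kcal_day * KCAL_DAY_TO_W
}

#' Time-resolved metabolic rate and per-distance cost
#'
#' Assembles the joint-space metabolic rate over the gait cycle:
#' internal work rate plus heat liberation rate plus (optionally) the
#' Harris-Benedict basal rate, then summarises it as a mean mass-normalized
#' rate (W·kg^-1) and a per-distance cost (J·kg^-1·m^-1, mean rate divided
#' by walking speed). The cycle mean is the arithmetic mean of the uniformly
#' spaced samples, which equals the trapezoidal integral on the periodic
#' grid.
#'
#' @param trial A [gait_trial()].
#' @param subject The matching [subject_profile()].
#' @param params A [parameter_set()].
#' @param norms A [normative_torques()].
#' @param include_basal Add the basal term (default `TRUE`, so the modelled
#'   quantity is gross, comparable with measured calorimetry).
#' @return An object of class `energy_breakdown`: `rate_series`,
#'   `work_rate_series`, `heat_rate_series` (W, length `n_samples`),
#'   `basal_rate` (W), `mean_rate` (W), `mean_rate_per_kg` (W·kg^-1) and
#'   `cost_per_kg_per_m` (J·kg^-1·m^-1).
#' @export
metabolic_rate_series <- function(trial, subject, params, norms,
                                  include_basal = TRUE) {
  h <- compute_heat_coefficients(subject, params, norms)
  work <- internal_work_rate(trial)
  heat <- heat_rate(trial, h)
  basal <- if (include_basal) basal_rate(subject) else 0
  rate <- work + heat + basal
  mean_rate <- mean(rate)
  structure(
    list(rate_series = rate, work_rate_series = work, heat_rate_series = heat,
         basal_rate = basal, mean_rate = mean_rate,
         mean_rate_per_kg = mean_rate / subject$mass,
         cost_per_kg_per_m = mean_rate / subject$mass / trial$speed),
    class = "energy_breakdown"
  )
}

#' Metabolic cost per unit distance
#'
#' Converts a mean metabolic rate into a per-distance cost:
#' (mean rate / mass) / speed.
#'
#' @param breakdown An `energy_breakdown`, or a mean total rate in W.
#' @param subject The [subject_profile()] (for mass).
#' @param speed Walking speed in m·s^-1, > 0.
#' @return Cost in J·kg^-1·m^-1.
#' @export
metabolic_cost <- function(breakdown, subject, speed) {
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0", call. = FALSE)
  mean_rate <- if (inherits(breakdown, "energy_breakdown")) {
    breakdown$mean_rate
  } else {
    as.numeric(breakdown)
  }
  mean_rate / subject$mass / speed
}
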