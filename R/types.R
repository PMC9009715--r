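#' Default degree-of-freedom labels
#'
#' The six lower-extremity degrees of freedom the model is driven by:
#' hip flexion, knee flexion and ankle dorsiflexion, bilaterally.
#'
#' @return Character vector of length 6.
#' @export
default_dof_labels <- function() {
  c("r_hip_flexion", "r_knee_flexion", "r_ankle_dorsiflexion",
    "l_hip_flexion", "l_knee_flexion", "l_ankle_dorsiflexion")
}

# Sex-averaged maximum isometric knee extension torques (N·m) used to impute
# tau_knee_max when it was not measured for a subject.
TAU_KNEE_MAX_MALE <- 212.4
TAU_KNEE_MAX_FEMALE <- 107.6

#' Subject profile
#'
#' Anthropometrics and maximum knee torque for one participant. The maximum
#' knee torque enters the heat-coefficient multiplier; when it was not
#' measured it is imputed from sex-averaged values (212.4 N·m for men,
#' 107.6 N·m for women).
#'
#' @param subject_id Identifier (coerced to character).
#' @param mass Body mass in kg; must be positive.
#' @param height Height in m; must be positive.
#' @param age Age in years; must be positive.
#' @param sex `"male"` or `"female"`.
#' @param tau_knee_max Maximum isometric knee extension torque in N·m, or
#'   `NULL`/`NA` to impute by sex.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, mass, height, age, sex,
                            tau_knee_max = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(is.numeric(mass), is.numeric(height), is.numeric(age))
  if (!(mass > 0 && height > 0 && age > 0)) {
    stop("mass, height and age must all be positive", call. = FALSE)
  }
  if (is.null(tau_knee_max) || is.na(tau_knee_max)) {
    tau_knee_max <- if (sex == "male") TAU_KNEE_MAX_MALE else TAU_KNEE_MAX_FEMALE
  }
  if (!is.finite(tau_knee_max) || tau_knee_max <= 0) {
    stop("tau_knee_max must be positive and finite", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), mass = mass, height = height,
         age = age, sex = sex, tau_knee_max = tau_knee_max),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %s, %.2f kg, %.2f m, %g yr, tau_knee_max %.1f N·m\n",
              x$subject_id, x$sex, x$mass, x$height, x$age, x$tau_knee_max))
  invisible(x)
}

#' Gait trial
#'
#' One averaged gait cycle for one subject and walking condition: joint
#' moments (N·m) and joint angular velocities (rad·s^-1) sampled at
#' `n_samples` uniformly spaced points over the cycle, for `n_dof` degrees
#' of freedom.
#'
#' @param subject_id Identifier matching a [subject_profile()].
#' @param speed Walking speed in m·s^-1 (> 0).
#' @param grade Treadmill grade in percent (signed; -8, 0 or +8 in the
#'   reference protocol, but unrestricted).
#' @param torques Numeric matrix `n_dof x n_samples` of joint moments (N·m).
#' @param velocities Numeric matrix of the same shape, joint angular
#'   velocities (rad·s^-1).
#' @param measured_rate Optional measured gross metabolic rate (W·kg^-1).
#' @param dof_labels Row labels; defaults to [default_dof_labels()] when the
#'   trial has six degrees of freedom.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, speed, grade, torques, velocities,
                       measured_rate = NULL, dof_labels = NULL) {
  torques <- as.matrix(torques)
  velocities <- as.matrix(velocities)
  if (!identical(dim(torques), dim(velocities))) {
    stop("torques and velocities must have identical dimensions", call. = FALSE)
  }
  if (!all(is.finite(torques)) || !all(is.finite(velocities))) {
    stop("torques and velocities must be finite everywhere", call. = FALSE)
  }
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0", call. = FALSE)
  n_dof <- nrow(torques)
  if (is.null(dof_labels)) {
    dof_labels <- if (n_dof == 6) default_dof_labels() else paste0("dof_", seq_len(n_dof))
  }
  if (length(dof_labels) != n_dof) {
    stop("dof_labels length must equal the number of torque rows", call. = FALSE)
  }
  rownames(torques) <- rownames(velocities) <- dof_labels
  structure(
    list(subject_id = as.character(subject_id), speed = speed, grade = grade,
         torques = torques, velocities = velocities,
         measured_rate = measured_rate, dof_labels = dof_labels),
    class = "gait_trial"
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s, %.1f m/s, %+g%% grade, %d DOF x %d samples%s\n",
              x$subject_id, x$speed, x$grade, nrow(x$torques), ncol(x$torques),
              if (is.null(x$measured_rate)) "" else
                sprintf(", measured %.2f W/kg", x$measured_rate)))
  invisible(x)
}

# canonical serialization order of the weighting vector
PARAM_NAMES <- c("w0am", "w1am", "w2am", "w3am", "w4am",
                 "w0sl", "w1sl", "w2sl", "w3sl", "w4sl")

#' Weighting parameter set
#'
#' The ten weighting parameters of the subject-specific heat coefficients:
#' five for the torque-dependent (`am`) family and five for the joint-power
#' (`sl`) family. `w0`–`w3` form a linear combination of the intercept,
#' mass, age and height; `w4` scales the normalized-torque multiplier.
#'
#' @param w Named or positional numeric vector of length 10, in the order
#'   `w0am, w1am, w2am, w3am, w4am, w0sl, w1sl, w2sl, w3sl, w4sl`.
#' @param label Optional text label.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(w, label = "") {
  w <- unlist(w)
  if (length(w) != 10) stop("a parameter set has exactly 10 entries", call. = FALSE)
  if (!is.null(names(w)) && all(nzchar(names(w)))) {
    if (!setequal(names(w), PARAM_NAMES)) {
      stop("parameter names must be ", paste(PARAM_NAMES, collapse = ", "),
           call. = FALSE)
    }
    w <- w[PARAM_NAMES]
  } else {
    names(w) <- PARAM_NAMES
  }
  if (!all(is.finite(w))) stop("all weighting parameters must be finite", call. = FALSE)
  structure(list(w = w, label = label), class = "parameter_set")
}

#' @export
as.numeric.parameter_set <- function(x, ...) x$w

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set>%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  print(signif(x$w, 4))
  invisible(x)
}

#' Normative maximum torques
#'
#' Population reference torques entering the heat-coefficient multiplier:
#' the average human's maximum knee torque and the average maximum torque of
#' each modelled degree of freedom. The source study does not print these
#' values, so the defaults are a documented stand-in (160 N·m, the mean of
#' the sex-averaged knee torques, uniformly for every degree of freedom);
#' the calibrated `w4` weights absorb this scale.
#'
#' @param tau_knee_avg_max Average maximum knee torque (N·m), > 0.
#' @param tau_i_avg_max Vector of average per-DOF maximum torques (N·m),
#'   all > 0; recycled scalars allowed via `n_dof`.
#' @param n_dof Number of degrees of freedom when `tau_i_avg_max` is scalar.
#' @return An object of class `normative_torques`.
#' @export
normative_torques <- function(tau_knee_avg_max = 160,
                              tau_i_avg_max = 160, n_dof = 6) {
  if (length(tau_i_avg_max) == 1) tau_i_avg_max <- rep(tau_i_avg_max, n_dof)
  if (!(tau_knee_avg_max > 0) || !all(tau_i_avg_max > 0)) {
    stop("normative torques must all be positive", call. = FALSE)
  }
  structure(list(tau_knee_avg_max = tau_knee_avg_max,
                 tau_i_avg_max = tau_i_avg_max),
            class = "normative_torques")
}
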