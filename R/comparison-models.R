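#' Walking condition for the empirical equations
#'
#' @param speed Walking speed in m·s^-1, > 0.
#' @param grade Grade in percent (signed).
#' @param load Carried load in kg (default 0).
#' @param terrain_coeff Dimensionless terrain coefficient (1 for a treadmill).
#' @return An object of class `walking_condition`.
#' @export
walking_condition <- function(speed, grade = 0, load = 0, terrain_coeff = 1) {
  if (!is.numeric(speed) || speed <= 0) stop("speed must be > 0", call. = FALSE)
  structure(list(speed = speed, grade = grade, load = load,
                 terrain_coeff = terrain_coeff),
            class = "walking_condition")
}

#' Pandolf load-carriage metabolic cost
#'
#' Classic load-carriage metabolic rate
#' `M_rate = 1.5 M + 2.0 (M+L)(L/M)^2 + eta (M+L)(1.5 V^2 + 0.35 V G)` watts,
#' converted to per-distance cost by dividing by mass and speed. With no
#' load the cost is mass-independent. The classic equation applies to
#' non-negative grades; negative grades require a downhill correction term,
#' supplied via `downhill_correction` (a `function(mass, cond)` returning
#' watts to add). Without one, a negative grade is an error rather than a
#' silent extrapolation.
#'
#' @param mass Body mass in kg.
#' @param cond A [walking_condition()].
#' @param downhill_correction Optional correction hook for negative grades.
#' @return Cost in J·kg^-1·m^-1.
#' @export
pandolf_cost <- function(mass, cond, downhill_correction = NULL) {
  v <- cond$speed; g <- cond$grade; l <- cond$load; eta <- cond$terrain_coeff
  if (g < 0 && is.null(downhill_correction)) {
    stop("the Pandolf equation does not cover negative grades; ",
         "supply a downhill_correction", call. = FALSE)
  }
  rate <- 1.5 * mass + 2.0 * (mass + l) * (l / mass)^2 +
    eta * (mass + l) * (1.5 * v^2 + 0.35 * v * g)
  if (g < 0) rate <- rate + downhill_correction(mass, cond)
  rate / (mass * v)
}

#' Looney level-walking metabolic cost
#'
#' Level-walking metabolic rate `1.44 + 1.94 S^0.43 + 0.24 S^4` W·kg^-1,
#' divided by speed to give a per-distance cost. A grade extension can be supplied as `grade_terms`, a
#' `function(cond)` returning additional W·kg^-1; without one a non-zero
#' grade is an error.
#'
#' @param cond A [walking_condition()].
#' @param grade_terms Optional grade-term hook.
#' @return Cost in J·kg^-1·m^-1.
#' @export
looney_cost <- function(cond, grade_terms = NULL) {
  s <- cond$speed
  if (s <= 0) stop("speed must be > 0", call. = FALSE)
  if (cond$grade != 0 && is.null(grade_terms)) {
    stop("the core Looney equation covers level walking only; ",
         "supply grade_terms for non-zero grades", call. = FALSE)
  }
  rate <- 1.44 + 1.94 * s^0.43 + 0.24 * s^4
  if (cond$grade != 0) rate <- rate + grade_terms(cond)
  rate / s
}

#' Per-model summary and error table
#'
#' Evaluates each prediction model over a set of (subject, condition) trials
#' and summarises, per model and condition label, the prediction mean,
#' sample standard deviation, and RMSE against the measured costs.
#'
#' @param models Named list of `function(subject, cond)` returning a cost in
#'   J·kg^-1·m^-1 (the subject argument may be ignored by mass-free models).
#' @param subjects List of [subject_profile()], one per trial.
#' @param conditions List of [walking_condition()], one per trial.
#' @param measured Numeric vector of measured costs, one per trial.
#' @param condition_labels Optional grouping labels per trial; default
#'   derives `downhill`/`level`/`uphill` from the sign of the grade.
#' @return Data frame with columns `model`, `condition`, `n`, `mean`, `sd`,
#'   `rmse`.
#' @export
model_comparison_table <- function(models, subjects, conditions, measured,
                                   condition_labels = NULL) {
  n <- length(conditions)
  if (n == 0) stop("no trials supplied", call. = FALSE)
  stopifnot(length(subjects) == n, length(measured) == n)
  if (is.null(condition_labels)) {
    grades <- vapply(conditions, `[[`, 0, "grade")
    condition_labels <- ifelse(grades > 0, "uphill",
                               ifelse(grades < 0, "downhill", "level"))
  }
  rows <- list()
  for (m in names(models)) {
    pred <- vapply(seq_len(n), function(j) {
      models[[m]](subjects[[j]], conditions[[j]])
    }, 0)
    for (lab in unique(condition_labels)) {
      k <- condition_labels == lab
      rows[[length(rows) + 1]] <- data.frame(
        model = m, condition = lab, n = sum(k),
        mean = mean(pred[k]),
        sd = stats::sd(pred[k]),
        rmse = rmse(pred[k], measured[k])
      )
    }
  }
  do.call(rbind, rows)
}
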