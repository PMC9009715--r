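#' Parameter-recovery experiment against the synthetic generator
#'
#' Closes the loop between the synthetic generator and the calibrator: a
#' training set of `2 * n_subjects` trials (two speeds per subject) at one
#' grade is generated from a known feasible ground-truth parameter set with
#' multiplicative noise on the measured costs, the weighting parameters are
#' calibrated on it, and the fitted model is scored on held-out data.
#'
#' Two held-out designs are available. `"fresh_trials"` (the recovery
#' default) generates new waveforms and new noise for the same cohort and
#' scores the fitted mapping on them — a predictive check whose error is
#' governed by the injected noise. `"new_subjects"` additionally draws a
#' separate validation cohort, which folds anthropometric extrapolation of
#' the subject-specific coefficient surfaces into the score; with a handful
#' of training subjects that extrapolation has unbounded leverage under
#' noise, so it is reported rather than bounded.
#'
#' @param grade Grade in percent of the calibrated condition.
#' @param noise_sd Multiplicative noise SD on measured costs (e.g. 0.02).
#' @param seed Master seed for the whole experiment.
#' @param n_subjects Training cohort size (default 8, two speeds each).
#' @param n_valid_subjects Validation cohort size for `"new_subjects"`.
#' @param speeds Walking speeds, m·s^-1.
#' @param holdout `"fresh_trials"` or `"new_subjects"`.
#' @param true_params Feasible ground-truth [parameter_set()].
#' @param wspec A [waveform_spec()]; its `noise_sd` is overridden by
#'   `noise_sd`.
#' @param norms,policy,config Passed to [calibrate()].
#' @return List: `calibration` (the [calibrate()] result), `train_rmse`,
#'   `validation_rmse`, `noise_floor` (`noise_sd` times the mean held-out
#'   measured cost), `mean_cost`, `n_train`, `n_valid`.
#' @export
recovery_experiment <- function(grade = 0, noise_sd = 0.02, seed = 0,
                                n_subjects = 8, n_valid_subjects = 4,
                                speeds = c(0.8, 1.3),
                                holdout = c("fresh_trials", "new_subjects"),
                                true_params = synthetic_truth_params(),
                                wspec = waveform_spec(),
                                norms = normative_torques(),
                                policy = emax_policy(),
                                config = calibration_config(seed = seed)) {
  holdout <- match.arg(holdout)
  wspec$noise_sd <- noise_sd

  make_trials <- function(subjects) {
    trials <- list()
    for (id in names(subjects)) {
      for (v in speeds) {
        tr <- generate_trial(subjects[[id]], v, grade, wspec, seed = NULL)
        cost <- generate_measured_cost(tr, subjects[[id]], true_params,
                                       norms, noise_sd, seed = NULL)
        tr$measured_rate <- cost * v
        trials[[length(trials) + 1]] <- tr
      }
    }
    trials
  }

  withr::with_seed(seed, {
    cohort <- generate_cohort(cohort_spec(n_subjects = n_subjects, seed = NULL))
    train_trials <- make_trials(cohort)
    if (holdout == "fresh_trials") {
      valid_subjects <- cohort
    } else {
      extra <- generate_cohort(cohort_spec(n_subjects = n_valid_subjects,
                                           seed = NULL))
      names(extra) <- sprintf("V%02d", seq_along(extra))
      for (k in seq_along(extra)) extra[[k]]$subject_id <- names(extra)[k]
      valid_subjects <- extra
    }
    valid_trials <- make_trials(valid_subjects)

    training <- training_set(train_trials, cohort)
    result <- calibrate(training, norms, policy, config)

    validation <- training_set(valid_trials, valid_subjects,
                               condition = training$condition)
    pred <- predict_costs(result$params, validation, norms)
    list(calibration = result,
         train_rmse = rmse(result$model_cost, result$measured_cost),
         validation_rmse = rmse(pred, validation$measured_cost),
         noise_floor = noise_sd * mean(validation$measured_cost),
         mean_cost = mean(validation$measured_cost),
         n_train = training$n_trials,
         n_valid = validation$n_trials)
  })
}
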