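#' Pipeline configuration
#'
#' Settings for the end-to-end calibrate/validate/compare pipeline. The
#' train/validation split is by subject, never by trial, so all of a
#' subject's conditions stay on one side of the split; the default takes the
#' first two thirds of the subject ids for training (8 of 12 in the
#' reference layout, sex-balanced when the cohort alternates sexes).
#'
#' @param training_ids,validation_ids Character vectors of subject ids, or
#'   `NULL` for the default split.
#' @param norms A [normative_torques()].
#' @param policy An [emax_policy()].
#' @param calibration A [calibration_config()].
#' @param include_basal Include the basal term in modelled costs.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(training_ids = NULL, validation_ids = NULL,
                            norms = normative_torques(),
                            policy = emax_policy(),
                            calibration = calibration_config(),
                            include_basal = TRUE) {
  structure(list(training_ids = training_ids, validation_ids = validation_ids,
                 norms = norms, policy = policy, calibration = calibration,
                 include_basal = include_basal),
            class = "pipeline_config")
}

condition_label <- function(grade) {
  if (grade > 0) "uphill" else if (grade < 0) "downhill" else "level"
}

#' Run the full calibration-validation pipeline
#'
#' For each walking condition (grade) in the study: calibrates a weighting
#' parameter set on the training subjects' trials, predicts the validation
#' subjects' costs, and reports training/validation RMSE, a Bland-Altman
#' agreement analysis of the validation predictions, and the empirical
#' comparison models where they apply (Pandolf on non-negative grades,
#' Looney on level walking). An infeasible calibration does not abort the
#' pipeline; the condition is flagged and reported.
#'
#' @param study A list with `subjects` (named list of [subject_profile()])
#'   and `trials` (list of [gait_trial()] carrying `measured_rate`), e.g.
#'   from [generate_study()] or [read_study()].
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: per-condition list with the
#'   [calibrate()] result, validation predictions, `rmse_table` and
#'   Bland-Altman report, plus an overall `rmse_table` and `comparison`
#'   table.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  subjects <- study$subjects
  trials <- study$trials
  ids <- names(subjects)
  train_ids <- config$training_ids
  valid_ids <- config$validation_ids
  if (is.null(train_ids)) train_ids <- ids[seq_len(round(2 / 3 * length(ids)))]
  if (is.null(valid_ids)) valid_ids <- setdiff(ids, train_ids)
  if (!length(train_ids) || !length(valid_ids)) {
    stop("both training and validation splits must be non-empty", call. = FALSE)
  }
  overlap <- intersect(train_ids, valid_ids)
  if (length(overlap)) {
    stop("subjects in both splits: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }

  grades <- sort(unique(vapply(trials, `[[`, 0, "grade")))
  conditions <- list()
  rmse_rows <- list()
  comp_subjects <- list(); comp_conditions <- list(); comp_measured <- numeric(0)

  for (g in grades) {
    lab <- condition_label(g)
    sel <- vapply(trials, function(tr) tr$grade == g, TRUE)
    cond_trials <- trials[sel]
    in_train <- vapply(cond_trials, function(tr) tr$subject_id %in% train_ids, TRUE)
    tr_train <- cond_trials[in_train]
    tr_valid <- cond_trials[!in_train]
    if (!length(tr_train) || !length(tr_valid)) {
      stop("condition ", lab, " lacks a training or validation trial",
           call. = FALSE)
    }

    training <- training_set(tr_train, subjects, condition = lab)
    result <- calibrate(training, config$norms, config$policy,
                        config$calibration, config$include_basal)

    validation <- training_set(tr_valid, subjects, condition = lab)
    pred <- predict_costs(result$params, validation, config$norms,
                          config$include_basal)
    meas <- validation$measured_cost

    rmse_rows[[lab]] <- data.frame(
      condition = lab,
      training_n = training$n_trials,
      training_rmse = rmse(result$model_cost, result$measured_cost),
      validation_n = validation$n_trials,
      validation_rmse = rmse(pred, meas),
      feasible = result$feasible
    )
    conditions[[lab]] <- list(
      grade = g,
      calibration = result,
      validation_predicted = pred,
      validation_measured = meas,
      bland_altman = bland_altman(pred, meas)
    )

    for (tr in tr_valid) {
      comp_subjects[[length(comp_subjects) + 1]] <- subjects[[tr$subject_id]]
      comp_conditions[[length(comp_conditions) + 1]] <-
        walking_condition(tr$speed, tr$grade)
      comp_measured <- c(comp_measured, tr$measured_rate / tr$speed)
    }
  }

  models <- list(
    pandolf = function(s, cond) {
      if (cond$grade < 0) return(NA_real_)
      pandolf_cost(s$mass, cond)
    },
    looney = function(s, cond) {
      if (cond$grade != 0) return(NA_real_)
      looney_cost(cond)
    }
  )
  comparison <- model_comparison_table_na(models, comp_subjects,
                                          comp_conditions, comp_measured)

  structure(list(conditions = conditions,
                 rmse_table = do.call(rbind, rmse_rows),
                 comparison = comparison,
                 training_ids = train_ids, validation_ids = valid_ids,
                 seed = config$calibration$seed),
            class = "pipeline_result")
}

# comparison table tolerant of models that do not cover a condition
model_comparison_table_na <- function(models, subjects, conditions, measured) {
  grades <- vapply(conditions, `[[`, 0, "grade")
  labs <- ifelse(grades > 0, "uphill", ifelse(grades < 0, "downhill", "level"))
  rows <- list()
  for (m in names(models)) {
    pred <- vapply(seq_along(conditions), function(j) {
      models[[m]](subjects[[j]], conditions[[j]])
    }, 0)
    for (lab in unique(labs)) {
      k <- labs == lab & !is.na(pred)
      if (!any(k)) next
      rows[[length(rows) + 1]] <- data.frame(
        model = m, condition = lab, n = sum(k), mean = mean(pred[k]),
        sd = stats::sd(pred[k]), rmse = rmse(pred[k], measured[k]))
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$rmse_table, row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs as CSV
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$rmse_table, file.path(dir, "rmse.csv"),
                   row.names = FALSE)
  if (!is.null(result$comparison)) {
    utils::write.csv(result$comparison, file.path(dir, "comparison.csv"),
                     row.names = FALSE)
  }
  for (lab in names(result$conditions)) {
    cond <- result$conditions[[lab]]
    utils::write.csv(
      data.frame(predicted = cond$validation_predicted,
                 measured = cond$validation_measured,
                 difference = cond$bland_altman$differences),
      file.path(dir, paste0("validation_", lab, ".csv")), row.names = FALSE)
    w <- cond$calibration$params$w
    utils::write.csv(data.frame(parameter = names(w), value = unname(w)),
                     file.path(dir, paste0("params_", lab, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
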