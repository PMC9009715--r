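#' Write a gait trial to CSV
#'
#' One row per gait-cycle percent (0-99), one `<dof>_moment` (N·m) and one
#' `<dof>_velocity` (rad·s^-1) column per degree of freedom.
#'
#' @param trial A [gait_trial()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  n <- ncol(trial$torques)
  df <- data.frame(percent = seq_len(n) - 1L)
  for (i in seq_along(trial$dof_labels)) {
    df[[paste0(trial$dof_labels[i], "_moment")]] <- trial$torques[i, ]
    df[[paste0(trial$dof_labels[i], "_velocity")]] <- trial$velocities[i, ]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gait trial from CSV
#'
#' Parses the per-trial waveform layout written by [write_trial()]: a
#' `percent` column (strictly increasing, `n_samples` rows) plus paired
#' `<dof>_moment` / `<dof>_velocity` columns. Columns are matched by header
#' name, so their order in the file is free. Malformed files fail with the
#' offending row or column named.
#'
#' @param path CSV path.
#' @param subject_id,speed,grade Trial metadata (not stored in the waveform
#'   file).
#' @param measured_rate Optional measured metabolic rate, W·kg^-1.
#' @param dof_labels Expected degrees of freedom; default
#'   [default_dof_labels()].
#' @param n_samples Expected number of rows (default 100).
#' @return A [gait_trial()].
#' @export
read_trial <- function(path, subject_id, speed, grade, measured_rate = NULL,
                       dof_labels = default_dof_labels(), n_samples = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) != n_samples) {
    stop(sprintf("%s: expected %d data rows, found %d", path, n_samples,
                 nrow(df)), call. = FALSE)
  }
  if (!"percent" %in% names(df)) stop(path, ": missing 'percent' column",
                                      call. = FALSE)
  if (any(diff(df$percent) <= 0)) {
    stop(path, ": 'percent' must be strictly increasing", call. = FALSE)
  }
  need <- c(paste0(dof_labels, "_moment"), paste0(dof_labels, "_velocity"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (cn in need) {
    col <- df[[cn]]
    if (!is.numeric(col) || anyNA(col)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("%s: non-numeric or missing value in column '%s', row %d",
                   path, cn, if (is.na(bad)) NA_integer_ else bad),
           call. = FALSE)
    }
  }
  torques <- t(as.matrix(df[paste0(dof_labels, "_moment")]))
  velocities <- t(as.matrix(df[paste0(dof_labels, "_velocity")]))
  gait_trial(subject_id, speed, grade, torques, velocities,
             measured_rate = measured_rate, dof_labels = dof_labels)
}

#' Write a synthetic study to a directory
#'
#' Writes `subjects.csv`, `trials.csv` (the manifest) and one waveform CSV
#' per trial.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subj <- do.call(rbind, lapply(study$subjects, function(s) {
    data.frame(subject_id = s$subject_id, sex = s$sex, mass = s$mass,
               height = s$height, age = s$age, tau_knee_max = s$tau_knee_max)
  }))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  rows <- lapply(seq_along(study$trials), function(j) {
    tr <- study$trials[[j]]
    fname <- sprintf("trial_%s_v%03d_g%+03d.csv", tr$subject_id,
                     round(100 * tr$speed), tr$grade)
    write_trial(tr, file.path(dir, fname))
    data.frame(subject_id = tr$subject_id, speed = tr$speed, grade = tr$grade,
               trial_file = fname,
               measured_rate = if (is.null(tr$measured_rate)) NA else tr$measured_rate)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "trials.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a study directory
#'
#' Reads the manifest written by [write_study()] back into subjects and
#' trials. Every trial must reference an existing subject and file.
#'
#' @param dir Study directory.
#' @return List with `subjects` (named list of [subject_profile()]) and
#'   `trials` (list of [gait_trial()]).
#' @export
read_study <- function(dir) {
  subj_df <- utils::read.csv(file.path(dir, "subjects.csv"))
  subjects <- stats::setNames(lapply(seq_len(nrow(subj_df)), function(k) {
    r <- subj_df[k, ]
    subject_profile(r$subject_id, r$mass, r$height, r$age, r$sex,
                    tau_knee_max = if ("tau_knee_max" %in% names(r)) r$tau_knee_max else NULL)
  }), subj_df$subject_id)
  man <- utils::read.csv(file.path(dir, "trials.csv"))
  trials <- lapply(seq_len(nrow(man)), function(k) {
    r <- man[k, ]
    if (!r$subject_id %in% names(subjects)) {
      stop("trial references unknown subject ", r$subject_id, call. = FALSE)
    }
    fp <- file.path(dir, r$trial_file)
    if (!file.exists(fp)) stop("missing trial file ", fp, call. = FALSE)
    read_trial(fp, r$subject_id, r$speed, r$grade,
               measured_rate = if (is.na(r$measured_rate)) NULL else r$measured_rate)
  })
  list(subjects = subjects, trials = trials)
}

#' Packaged weighting parameter sets
#'
#' Parameter-set fixtures shipped with the package: the original level-walking
#' calibration (`"roberts2016"`), published swarm-stage initial values
#' (`"swarm_initial_level"`, `"swarm_initial_uphill"`,
#' `"swarm_initial_downhill"`) and published per-condition optimal sets
#' (`"level"`, `"uphill"`, `"downhill"`).
#'
#' @return Character vector of available labels.
#' @export
list_parameter_sets <- function() {
  names(read_param_fixtures())
}

read_param_fixtures <- function() {
  path <- system.file("extdata", "parameter_sets.json", package = "jointmee",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Load a packaged parameter set by label
#'
#' @param label One of [list_parameter_sets()].
#' @return A [parameter_set()].
#' @export
load_parameter_set <- function(label) {
  fixtures <- read_param_fixtures()
  if (!label %in% names(fixtures)) {
    stop("unknown parameter set '", label, "'; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  }
  parameter_set(unlist(fixtures[[label]]), label = label)
}
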