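#' Training set for heat-coefficient calibration
#'
#' Bundles the trials of one walking condition with their subjects and
#' measured per-distance metabolic costs. When `measured_cost` is omitted it
#' is derived from each trial's `measured_rate` divided by its speed (the
#' single point where W·kg^-1 is converted to J·kg^-1·m^-1).
#'
#' @param trials List of [gait_trial()] objects, all at the condition's grade.
#' @param subjects Named list of [subject_profile()] objects keyed by
#'   `subject_id` (or an unnamed list; ids are taken from the profiles).
#' @param measured_cost Optional numeric vector, J·kg^-1·m^-1, one per trial.
#' @param condition Condition label; inferred from the common grade
#'   (`"downhill"`, `"level"`, `"uphill"`) when omitted.
#' @return An object of class `training_set`.
#' @export
training_set <- function(trials, subjects, measured_cost = NULL,
                         condition = NULL) {
  if (length(trials) == 0) stop("training set must contain trials", call. = FALSE)
  if (is.null(names(subjects)) || !all(nzchar(names(subjects)))) {
    names(subjects) <- vapply(subjects, `[[`, "", "subject_id")
  }
  ids <- vapply(trials, `[[`, "", "subject_id")
  missing <- setdiff(unique(ids), names(subjects))
  if (length(missing)) {
    stop("no subject profile for trial subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grades <- vapply(trials, `[[`, 0, "grade")
  if (length(unique(grades)) != 1) {
    stop("all trials in a training set must share one grade", call. = FALSE)
  }
  if (is.null(condition)) {
    condition <- if (grades[1] > 0) "uphill" else if (grades[1] < 0) "downhill" else "level"
  }
  if (is.null(measured_cost)) {
    measured_cost <- vapply(trials, function(tr) {
      if (is.null(tr$measured_rate)) {
        stop("trial for subject ", tr$subject_id,
             " has no measured rate and no measured_cost was supplied",
             call. = FALSE)
      }
      tr$measured_rate / tr$speed
    }, 0)
  }
  if (length(measured_cost) != length(trials) || !all(measured_cost > 0)) {
    stop("measured_cost must be positive, one value per trial", call. = FALSE)
  }
  structure(
    list(condition = condition, trials = trials,
         subjects = subjects[unique(ids)], measured_cost = measured_cost,
         n_trials = length(trials)),
    class = "training_set"
  )
}

#' Upper-bound policy for modelled metabolic cost
#'
#' Per (condition, speed) multiplier of the measured cost that caps the
#' modelled cost during calibration (the stand-in for a VO2max-derived
#' ceiling). Defaults: 110% of the measured cost everywhere except downhill
#' walking at 1.3 m·s^-1, which uses 115%.
#'
#' @param table Data frame with columns `condition`, `speed`, `fraction`
#'   (all fractions >= 1).
#' @return An object of class `emax_policy`.
#' @export
emax_policy <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(
      condition = c("level", "level", "uphill", "uphill", "downhill", "downhill"),
      speed = c(0.8, 1.3, 0.8, 1.3, 0.8, 1.3),
      fraction = c(1.10, 1.10, 1.10, 1.10, 1.10, 1.15)
    )
  }
  stopifnot(all(c("condition", "speed", "fraction") %in% names(table)))
  if (!all(table$fraction >= 1)) stop("all fractions must be >= 1", call. = FALSE)
  structure(list(table = table), class = "emax_policy")
}

#' Look up the upper-bound fraction for a condition and speed
#'
#' @param policy An [emax_policy()].
#' @param condition Condition label.
#' @param speed Walking speed in m·s^-1.
#' @return The fraction (scalar >= 1).
#' @export
emax_fraction <- function(policy, condition, speed) {
  tab <- policy$table
  hit <- tab$condition == condition & abs(tab$speed - speed) < 1e-9
  if (!any(hit)) {
    stop(sprintf("no upper-bound fraction configured for condition '%s' at %.3g m/s",
                 condition, speed), call. = FALSE)
  }
  tab$fraction[which(hit)[1]]
}

#' Least-squares calibration objective
#'
#' Mean squared residual between measured and modelled per-distance cost
#' over the training set: `sum((E_ex - E_m)^2) / N`.
#'
#' @param params A [parameter_set()].
#' @param training A [training_set()].
#' @param norms A [normative_torques()].
#' @param include_basal Include the basal term in the modelled cost
#'   (default `TRUE`).
#' @return Scalar objective value, (J·kg^-1·m^-1)^2.
#' @export
mee_objective <- function(params, training, norms = normative_torques(),
                          include_basal = TRUE) {
  if (training$n_trials == 0) stop("empty training set", call. = FALSE)
  em <- predict_costs(params, training, norms, include_basal)
  sum((training$measured_cost - em)^2) / training$n_trials
}

#' Modelled per-distance costs over a training set
#'
#' @inheritParams mee_objective
#' @return Numeric vector, one modelled cost (J·kg^-1·m^-1) per trial.
#' @export
predict_costs <- function(params, training, norms = normative_torques(),
                          include_basal = TRUE) {
  vapply(training$trials, function(tr) {
    subj <- training$subjects[[tr$subject_id]]
    metabolic_rate_series(tr, subj, params, norms, include_basal)$cost_per_kg_per_m
  }, 0)
}

#' Non-negativity margins of the linear coefficient parts
#'
#' The two linear combinations `w0 + w1*M + w2*A + w3*H` (one per heat
#' coefficient family) for one subject. Both must be non-negative for the
#' heat coefficients to be admissible.
#'
#' @param subject A [subject_profile()].
#' @param params A [parameter_set()].
#' @return Named numeric vector `c(am = ..., sl = ...)`.
#' @export
linear_coefficient_margins <- function(subject, params) {
  w <- params$w
  c(am = w[["w0am"]] + w[["w1am"]] * subject$mass +
      w[["w2am"]] * subject$age + w[["w3am"]] * subject$height,
    sl = w[["w0sl"]] + w[["w1sl"]] * subject$mass +
      w[["w2sl"]] * subject$age + w[["w3sl"]] * subject$height)
}

#' Non-negativity margins of the normalized-torque multipliers
#'
#' Per-DOF values of `1 + w4 * (tau_knee_max / tau_knee_avg_max) *
#' tau_i_avg_max` for both coefficient families.
#'
#' @inheritParams compute_heat_coefficients
#' @return Named list with numeric vectors `am` and `sl`, one margin per DOF.
#' @export
multiplier_margins <- function(subject, params, norms) {
  w <- params$w
  ratio <- subject$tau_knee_max / norms$tau_knee_avg_max
  list(am = 1 + w[["w4am"]] * ratio * norms$tau_i_avg_max,
       sl = 1 + w[["w4sl"]] * ratio * norms$tau_i_avg_max)
}

#' Worst no-recharge margin of a trial
#'
#' Minimum over all degrees of freedom and time samples of the per-DOF
#' instantaneous metabolic term `tau*qdot + h_am*|tau| + h_sl*|tau*qdot|`.
#' Non-negative everywhere means the model never recovers metabolic energy
#' from negative joint work.
#'
#' @param trial A [gait_trial()].
#' @param h A `heat_coefficients` object.
#' @return Scalar worst margin (W).
#' @export
no_recharge_margin <- function(trial, h) {
  p <- trial$torques * trial$velocities
  min(p + h$h_am * abs(trial$torques) + h$h_sl * abs(p))
}

#' Per-trial bound margins on the modelled cost
#'
#' Lower margin `E_m >= 0` and upper margin `E_max - E_m >= 0`, with
#' `E_max = fraction * E_ex`.
#'
#' @param model_cost Modelled costs, J·kg^-1·m^-1.
#' @param measured_cost Measured costs, same length.
#' @param fraction Upper-bound fraction(s), recycled.
#' @return List with numeric vectors `lower` and `upper`.
#' @export
emax_margins <- function(model_cost, measured_cost, fraction) {
  stopifnot(length(model_cost) == length(measured_cost))
  list(lower = model_cost, upper = fraction * measured_cost - model_cost)
}

#' Optimizer settings for heat-coefficient calibration
#'
#' @param swarm_size Number of particles in the global stage.
#' @param swarm_tol Relative stall tolerance on the best objective.
#' @param stall_iters Window (iterations) over which the stall tolerance is
#'   assessed.
#' @param max_iters Iteration cap for the swarm stage.
#' @param local_tol Relative function tolerance of the local refinement.
#' @param penalty_weight Quadratic constraint-penalty weight; `NULL` means
#'   `1e3 * mean(measured cost)^2`, which puts unit constraint violations on
#'   the objective's squared-cost scale.
#' @param seed Integer seed for swarm initialization.
#' @param init_range Particles start uniformly in `[-init_range, init_range]`
#'   per parameter (the search itself is unbounded).
#' @param local_rounds Number of penalty escalations (x10 each) in the local
#'   stage.
#' @param feas_tol Absolute feasibility tolerance on constraint margins.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(swarm_size = 100, swarm_tol = 1e-6,
                               stall_iters = 20, max_iters = 200,
                               local_tol = 1e-6, penalty_weight = NULL,
                               seed = 0, init_range = 10, local_rounds = 3,
                               feas_tol = 1e-8) {
  structure(list(swarm_size = swarm_size, swarm_tol = swarm_tol,
                 stall_iters = stall_iters, max_iters = max_iters,
                 local_tol = local_tol, penalty_weight = penalty_weight,
                 seed = seed, init_range = init_range,
                 local_rounds = local_rounds, feas_tol = feas_tol),
            class = "calibration_config")
}

# Precomputed per-trial summaries so the objective and constraints are cheap
# inside the optimizer: the modelled cost is affine in the per-subject heat
# coefficients, which collapse each trial to a handful of torque/power means.
build_design <- function(training, norms, policy, include_basal = TRUE) {
  subj_ids <- names(training$subjects)
  subj <- lapply(training$subjects, function(s) {
    list(M = s$mass, A = s$age, H = s$height,
         mult = s$tau_knee_max / norms$tau_knee_avg_max * norms$tau_i_avg_max)
  })
  trials <- lapply(training$trials, function(tr) {
    s <- training$subjects[[tr$subject_id]]
    p <- tr$torques * tr$velocities
    list(subject = match(tr$subject_id, subj_ids),
         mean_work = mean(internal_work_rate(tr)),
         basal = if (include_basal) basal_rate(s) else 0,
         mv = s$mass * tr$speed,
         b = rowMeans(abs(tr$torques)),     # mean |tau| per DOF
         cc = rowMeans(abs(p)),             # mean |tau*qdot| per DOF
         mult = s$tau_knee_max / norms$tau_knee_avg_max * norms$tau_i_avg_max,
         anthro = c(1, s$mass, s$age, s$height),
         abs_tau = abs(tr$torques), power = p, abs_power = abs(p))
  })
  for (j in seq_along(trials)) {
    tr <- training$trials[[j]]
    trials[[j]]$emax <- emax_fraction(policy, training$condition, tr$speed) *
      training$measured_cost[j]
  }
  list(subjects = subj, trials = trials,
       measured = training$measured_cost, n = training$n_trials)
}

# Objective, modelled costs and all constraint margins at one parameter
# vector, from the precomputed design.
eval_design <- function(w, design) {
  ns <- length(design$subjects)
  lin_am <- numeric(ns); lin_sl <- numeric(ns)
  h_am <- vector("list", ns); h_sl <- vector("list", ns)
  mult_margins <- numeric(0)
  for (s in seq_len(ns)) {
    sj <- design$subjects[[s]]
    lin_am[s] <- w[1] + w[2] * sj$M + w[3] * sj$A + w[4] * sj$H
    lin_sl[s] <- w[6] + w[7] * sj$M + w[8] * sj$A + w[9] * sj$H
    m_am <- 1 + w[5] * sj$mult
    m_sl <- 1 + w[10] * sj$mult
    h_am[[s]] <- lin_am[s] * m_am
    h_sl[[s]] <- lin_sl[s] * m_sl
    mult_margins <- c(mult_margins, m_am, m_sl)
  }
  nt <- design$n
  em <- numeric(nt); recharge <- numeric(nt); upper <- numeric(nt)
  for (j in seq_len(nt)) {
    tr <- design$trials[[j]]
    s <- tr$subject
    em[j] <- (tr$mean_work + tr$basal +
                sum(h_am[[s]] * tr$b) + sum(h_sl[[s]] * tr$cc)) / tr$mv
    recharge[j] <- min(tr$power + h_am[[s]] * tr$abs_tau +
                         h_sl[[s]] * tr$abs_power)
    upper[j] <- tr$emax - em[j]
  }
  list(objective = sum((design$measured - em)^2) / nt,
       em = em,
       margins = c(lin_am, lin_sl, mult_margins, recharge, em, upper))
}

penalized_objective <- function(w, design, weight) {
  ev <- eval_design(w, design)
  v <- pmin(ev$margins, 0)
  ev$objective + weight * sum(v * v)
}

# Variable projection: the modelled cost is bilinear in the weighting vector
# (linear in the eight w0..w3 weights once the two w4 multiplier weights are
# fixed), so for fixed (w4am, w4sl) the least-squares problem over the
# remaining eight is solved exactly. Returns the assembled 10-vector and the
# unconstrained objective at the inner optimum.
varpro_fit <- function(w4am, w4sl, design) {
  nt <- design$n
  X <- matrix(0, nt, 8)
  y <- numeric(nt)
  for (j in seq_len(nt)) {
    tr <- design$trials[[j]]
    fam <- (sum(tr$b) + w4am * sum(tr$mult * tr$b)) / tr$mv
    fsl <- (sum(tr$cc) + w4sl * sum(tr$mult * tr$cc)) / tr$mv
    X[j, ] <- c(fam * tr$anthro, fsl * tr$anthro)
    y[j] <- design$measured[j] - (tr$mean_work + tr$basal) / tr$mv
  }
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  w <- c(beta[1:4], w4am, beta[5:8], w4sl)
  list(w = w, objective = sum(fit$residuals^2) / nt)
}

#' Calibrate the heat-coefficient weighting parameters
#'
#' Solves the constrained least-squares problem for one walking condition in
#' two stages. Stage 1 is a global-best particle swarm (default 100
#' particles, no bounds, constraint violations folded in as an additive
#' quadratic penalty) that stops when the relative improvement of the best
#' penalized objective over a stall window drops below `swarm_tol`. Both
#' stages search a normalized parameter space (each weight divided by the
#' training-set mean of the quantity it multiplies) so the ten design
#' variables have comparable scale; reported parameters are unscaled. Stage 2
#' refines the swarm best with quasi-Newton (BFGS) minimization of the
#' penalized objective under an escalating penalty weight, then re-verifies
#' every constraint margin. If the refinement does not improve the merit at
#' the base penalty weight, the swarm solution is kept, so the staged
#' objective never increases.
#'
#' @param training A [training_set()].
#' @param norms A [normative_torques()].
#' @param policy An [emax_policy()].
#' @param config A [calibration_config()].
#' @param include_basal Include the basal term in the modelled cost.
#' @return An object of class `calibration_result`: calibrated
#'   [parameter_set()], objective value, feasibility flag, per-family worst
#'   constraint margins, seeds, evaluation counts and stage/iteration traces.
#' @export
calibrate <- function(training, norms = normative_torques(),
                      policy = emax_policy(), config = calibration_config(),
                      include_basal = TRUE) {
  design <- build_design(training, norms, policy, include_basal)
  base_weight <- config$penalty_weight
  if (is.null(base_weight)) base_weight <- 1e3 * mean(design$measured)^2

  # Internal variable scaling: search in a space where each parameter's
  # contribution to the linear part / multiplier is O(1), dividing by the
  # training-set mean of the quantity it multiplies. Reported parameters are
  # unscaled.
  mean_M <- mean(vapply(design$subjects, `[[`, 0, "M"))
  mean_A <- mean(vapply(design$subjects, `[[`, 0, "A"))
  mean_H <- mean(vapply(design$subjects, `[[`, 0, "H"))
  mean_mult <- mean(vapply(design$subjects, function(s) mean(s$mult), 0))
  scale <- rep(c(1, mean_M, mean_A, mean_H, mean_mult), 2)

  merit <- function(z, weight = base_weight) {
    penalized_objective(z / scale, design, weight)
  }
  n_evals <- 0L
  counted_merit <- function(z, weight = base_weight) {
    n_evals <<- n_evals + 1L
    merit(z, weight)
  }

  swarm <- withr::with_seed(config$seed, {
    run_pso(counted_merit, n_par = 10, config = config)
  })
  n_evals_swarm <- n_evals

  # Stage 2 starts from the swarm best plus a variable-projection candidate:
  # with the two w4 multiplier weights fixed, the model is linear in the
  # remaining eight weights, so the inner least squares is solved exactly
  # while a derivative-free outer search tunes (w4am, w4sl). Each candidate
  # is then pushed through escalating-penalty BFGS rounds so the constraints
  # are enforced, and the best penalized objective at the base weight wins.
  # R's optim reltol stops on slow *relative* progress, which in the shallow
  # quartic valleys of this objective triggers far from the minimizer; the
  # configured local_tol is applied as a stagnation test across rounds while
  # each BFGS run uses a much tighter internal tolerance.
  inner_ctl <- list(reltol = min(config$local_tol * 1e-6, 1e-12), maxit = 2000)

  vp_outer <- function(z4) {
    n_evals <<- n_evals + 1L
    varpro_fit(z4[1] / scale[5], z4[2] / scale[10], design)$objective
  }
  # profiled evaluations are cheap, so the 2-d outer search is multi-started
  # from a fixed grid plus the swarm's multiplier weights
  grid <- c(-1, -0.3, 0, 0.3, 1)
  starts <- rbind(as.matrix(expand.grid(grid, grid)),
                  swarm$best_par[c(5, 10)])
  vp_best <- NULL
  for (r in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[r, ], vp_outer,
                        control = list(reltol = 1e-12, maxit = 500))
    if (is.null(vp_best) || opt$value < vp_best$value) vp_best <- opt
  }
  vp_w <- varpro_fit(vp_best$par[1] / scale[5], vp_best$par[2] / scale[10],
                     design)$w
  candidates <- list(swarm$best_par, vp_w * scale)

  polish <- function(z0) {
    z <- z0
    for (k in seq_len(config$local_rounds)) {
      wk <- base_weight * 10^(k - 1)
      fit <- stats::optim(z, counted_merit, weight = wk, method = "BFGS",
                          control = inner_ctl)
      z <- fit$par
    }
    repeat {
      before <- merit(z)
      fit <- stats::optim(z, counted_merit, method = "BFGS",
                          control = inner_ctl)
      z <- fit$par
      if (before - fit$value <= config$local_tol * max(abs(before), 1e-12)) break
    }
    z
  }
  polished <- lapply(candidates, polish)
  refined <- polished[[which.min(vapply(polished, merit, 0))]]
  merit_swarm <- merit(swarm$best_par)
  merit_refined <- merit(refined)
  if (merit_refined > merit_swarm) refined <- swarm$best_par

  final <- eval_design(refined / scale, design)
  nt <- design$n
  n_lin <- 2 * length(design$subjects)
  fam <- rep(c("linear", "multiplier", "no_recharge", "cost_lower", "cost_upper"),
             c(n_lin, length(final$margins) - n_lin - 3 * nt, nt, nt, nt))
  worst <- tapply(final$margins, fam, min)[
    c("linear", "multiplier", "no_recharge", "cost_lower", "cost_upper")]
  feasible <- min(final$margins) >= -config$feas_tol

  params <- parameter_set(stats::setNames(refined / scale, PARAM_NAMES),
                          label = paste0("calibrated-", training$condition))
  structure(
    list(params = params,
         objective_value = final$objective,
         feasible = feasible,
         constraint_report = worst,
         worst_margin = min(final$margins),
         model_cost = final$em,
         measured_cost = design$measured,
         swarm_seed = config$seed,
         n_objective_evals = n_evals,
         stage_trace = c(after_swarm = merit_swarm,
                         after_refinement = min(merit_swarm, merit_refined)),
         swarm_trace = swarm$trace,
         n_swarm_evals = n_evals_swarm,
         condition = training$condition),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: objective %.4g (J/kg/m)^2, %s\n",
              x$condition, x$objective_value,
              if (x$feasible) "feasible" else
                sprintf("INFEASIBLE (worst margin %.3g)", x$worst_margin)))
  cat(sprintf("  swarm seed %d, %d objective evaluations\n",
              x$swarm_seed, x$n_objective_evals))
  invisible(x)
}

# Global-best particle swarm on an unbounded parameter space. Constriction
# coefficients follow the common Clerc-Kennedy setting.
run_pso <- function(fn, n_par, config) {
  np <- config$swarm_size
  inertia <- 0.7298
  c1 <- c2 <- 1.49618
  pos <- matrix(stats::runif(np * n_par, -config$init_range, config$init_range),
                nrow = np)
  vel <- matrix(stats::runif(np * n_par, -config$init_range, config$init_range),
                nrow = np) * 0.1
  fit <- apply(pos, 1, fn)
  pbest <- pos; pbest_fit <- fit
  g <- which.min(fit)
  gbest <- pos[g, ]; gbest_fit <- fit[g]
  trace <- gbest_fit
  for (it in seq_len(config$max_iters)) {
    r1 <- matrix(stats::runif(np * n_par), nrow = np)
    r2 <- matrix(stats::runif(np * n_par), nrow = np)
    vel <- inertia * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(gbest, np, n_par, byrow = TRUE) - pos)
    # velocity clamp keeps the unbounded swarm from diverging
    vmax <- config$init_range
    vel[vel > vmax] <- vmax
    vel[vel < -vmax] <- -vmax
    pos <- pos + vel
    fit <- apply(pos, 1, fn)
    improved <- fit < pbest_fit
    pbest[improved, ] <- pos[improved, ]
    pbest_fit[improved] <- fit[improved]
    g <- which.min(pbest_fit)
    if (pbest_fit[g] < gbest_fit) {
      gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
    }
    trace <- c(trace, gbest_fit)
    if (it > config$stall_iters) {
      prev <- trace[it + 1 - config$stall_iters]
      if ((prev - gbest_fit) <= config$swarm_tol * max(abs(prev), 1e-12)) break
    }
  }
  list(best_par = gbest, best_fit = gbest_fit, trace = trace)
}
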