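#' Fit a personalized glucose prediction model to a lifestyle log
#'
#' The main entry point: personalizes the glucose control model on a
#' patient's log by minimizing the full-window prediction RMSE (with model
#' restarts at fingersticks) over dimensionless parameter multipliers.
#' The pipeline is: global identification (brute-force grid or genetic
#' algorithm), optional Nelder--Mead simplex refinement, and optionally a
#' diurnal profile trained per day-period on top of the globally trained
#' parameters.
#'
#' @param log a [patient_log()] with CGMS measurements.
#' @param n_params 3, 6 or 9 (preset trainable subsets, see
#'   [parameter_space()]), or a character vector of parameter names.
#' @param method identification method: `"ga_slow"` (default), `"ga_fast"`
#'   or `"brute_force"`.
#' @param refine logical: refine the result by Nelder--Mead (max 100
#'   iterations).
#' @param diurnal logical: train a diurnal profile after global training.
#' @param diurnal_params parameter(s) to profile (default `"kxi"`, insulin
#'   sensitivity).
#' @param diurnal_config [training_config()] for the per-period runs
#'   (default the fast GA preset).
#' @param seed RNG seed; child stages are seeded deterministically from it.
#' @param lower,upper multiplier bounds.
#' @param reference reference [glycemia_params()].
#' @param absorption an [absorption_params()] vector (population-level,
#'   never trained).
#' @param step integration step, min.
#' @param ... overrides forwarded to [training_config()] for the global
#'   method.
#' @return An object of class `"glucose_fit"` with components
#'   `multipliers`, `params` (personalized absolute parameters), `profile`
#'   (a [diurnal_profile()] or NULL), `fitness` (mmol/l RMSE on the training
#'   log), `fitness_reference` (RMSE of the untrained reference model),
#'   `n_eval`, `stages` (audit trail) and the matched `call`.
#' @examples
#' vp <- generate_virtual_patient(days = 2, seed = 1)
#' fit <- glucose_fit(vp$log, n_params = 3, method = "ga_fast", seed = 1)
#' fit
#' coef(fit)
#' @export
glucose_fit <- function(log, n_params = 3,
                        method = c("ga_slow", "ga_fast", "brute_force"),
                        refine = TRUE, diurnal = FALSE,
                        diurnal_params = "kxi",
                        diurnal_config = training_config("ga_fast"),
                        seed = NULL, lower = 0.2, upper = 5,
                        reference = glycemia_params(),
                        absorption = absorption_params(), step = 1, ...) {
  stopifnot(inherits(log, "patient_log"))
  method <- match.arg(method)
  space <- parameter_space(n_params, lower, upper, reference)
  config <- training_config(method, seed = seed, ...)

  stages <- list()
  global <- if (method == "brute_force")
    brute_force(log, space, config, absorption = absorption, step = step)
  else
    ga_optimize(log, space, config, absorption = absorption, step = step)
  stages$global <- global

  if (refine) {
    nm <- nelder_mead_refine(log, space, global,
                             training_config("nelder_mead_refine"),
                             absorption = absorption, step = step)
    stages$refine <- nm
    global <- nm
  }

  params <- apply_multipliers(space, unname(global$multipliers))
  profile <- NULL
  if (diurnal) {
    dspace <- parameter_space(diurnal_params, lower, upper, params)
    dcfg <- diurnal_config
    if (is.null(dcfg$seed) && !is.null(seed)) dcfg$seed <- seed + 1000L
    dt <- train_diurnal(log, dspace, dcfg, refine_nm = refine,
                        absorption = absorption, step = step)
    profile <- dt$profile
    stages$diurnal <- dt$fit
  }

  final_fitness <- fitness(log, params, profile, absorption, step)
  structure(
    list(call = match.call(), log = log, space = space, method = method,
         multipliers = global$multipliers, params = params,
         profile = profile, fitness = final_fitness,
         fitness_reference = fitness(log, reference, NULL, absorption, step),
         n_eval = sum(vapply(stages, function(s) s$n_eval, numeric(1))),
         stages = stages, absorption = absorption, step = step,
         seed = seed),
    class = "glucose_fit")
}

#' @export
print.glucose_fit <- function(x, ...) {
  cat("Personalized glucose prediction model\n")
  cat(sprintf("  method: %s%s%s, %d trained parameter(s), %d evaluations\n",
              x$method,
              if (!is.null(x$stages$refine)) " + Nelder-Mead" else "",
              if (!is.null(x$profile)) " + diurnal profile" else "",
              length(x$multipliers), x$n_eval))
  cat(sprintf("  training RMSE: %.3f mmol/l (untrained reference: %.3f)\n",
              x$fitness, x$fitness_reference))
  cat("  multipliers:\n")
  print(round(x$multipliers, 4))
  invisible(x)
}

#' @export
coef.glucose_fit <- function(object, type = c("multipliers", "parameters"),
                             ...) {
  type <- match.arg(type)
  if (type == "multipliers") object$multipliers else object$params
}

#' @export
summary.glucose_fit <- function(object, ...) {
  ref <- object$space$reference
  tab <- data.frame(
    parameter = object$space$names,
    reference = as.numeric(ref[object$space$names]),
    multiplier = as.numeric(object$multipliers),
    trained = as.numeric(object$params[object$space$names]))
  structure(list(fit = object, table = tab), class = "summary.glucose_fit")
}

#' @export
print.summary.glucose_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTrained parameters:\n")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.null(x$fit$profile)) {
    cat("\n")
    print(x$fit$profile)
  }
  impr <- 100 * (1 - x$fit$fitness / x$fit$fitness_reference)
  cat(sprintf("\nRMSE improvement over the untrained model: %.1f%%\n", impr))
  invisible(x)
}

#' Predict glucose from a fitted model
#'
#' @param object a `"glucose_fit"`.
#' @param newdata a [patient_log()] (default: the training log).
#' @param protocol `"full"` for a continuous whole-log run paired with the
#'   CGMS, `"meal_wise"` for per-meal short-horizon predictions.
#' @param restart restart at fingersticks (full protocol only).
#' @param horizons meal-wise prediction horizons, min.
#' @param ... unused.
#' @return A `"prediction_result"` or `"meal_wise_result"`.
#' @export
predict.glucose_fit <- function(object, newdata = NULL,
                                protocol = c("full", "meal_wise"),
                                restart = TRUE,
                                horizons = c(60, 120, 240, 360), ...) {
  protocol <- match.arg(protocol)
  log <- if (is.null(newdata)) object$log else newdata
  if (protocol == "full")
    full_run(log, object$params, object$profile, restart = restart,
             absorption = object$absorption, step = object$step)
  else
    meal_wise_test(log, object$params, object$profile, horizons = horizons,
                   absorption = object$absorption, step = object$step)
}

#' @export
residuals.glucose_fit <- function(object, ...) {
  pr <- predict(object)
  pr$predicted - pr$reference
}

#' @export
fitted.glucose_fit <- function(object, ...) predict(object)$predicted

#' Simulate a trajectory from a fitted model
#'
#' Deterministic forward simulation of the personalized model over a log
#' (no measurement noise; use [generate_virtual_patient()] for noisy
#' synthetic data).
#'
#' @param object a `"glucose_fit"`.
#' @param nsim number of trajectories (identical unless inputs differ; kept
#'   for generic compatibility).
#' @param seed ignored (the forward model is deterministic).
#' @param newdata a [patient_log()] (default: the training log).
#' @param restart restart at fingersticks.
#' @param ... passed to [simulate_glucose()].
#' @return A `"glucose_trajectory"` (or a list of them when `nsim > 1`).
#' @export
simulate.glucose_fit <- function(object, nsim = 1, seed = NULL,
                                 newdata = NULL, restart = FALSE, ...) {
  log <- if (is.null(newdata)) object$log else newdata
  one <- function()
    simulate_glucose(log, object$params, object$absorption, object$profile,
                     step = object$step, restart = restart, ...)
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' Plot a fitted model against the CGMS trace
#'
#' @param x a `"glucose_fit"`.
#' @param newdata optional [patient_log()].
#' @param restart restart at fingersticks.
#' @param ... passed to `plot`.
#' @return Invisibly, the plotted `"prediction_result"`.
#' @export
plot.glucose_fit <- function(x, newdata = NULL, restart = TRUE, ...) {
  pr <- predict(x, newdata = newdata, restart = restart)
  plot(pr$time / 60, pr$reference, pch = 16, cex = 0.3, col = "grey40",
       xlab = "time (h)", ylab = "glucose (mmol/l)",
       main = "CGMS (points) vs model (line)", ...)
  lines(pr$time / 60, pr$predicted, col = "firebrick", lwd = 1.5)
  fs <- x$log$measurements[x$log$measurements$source == "fingerstick", ]
  if (!is.null(newdata))
    fs <- newdata$measurements[newdata$measurements$source == "fingerstick", ]
  if (nrow(fs)) points(fs$time / 60, fs$value, pch = 4, col = "blue")
  invisible(pr)
}
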