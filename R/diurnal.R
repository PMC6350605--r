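#' Diurnal parameter profile
#'
#' A 24-hour periodic multiplier curve for one or more model parameters,
#' capturing circadian variation (typically of insulin sensitivity, `kxi`).
#' The day is divided into equal periods (default four: 0-6 h, 6-12 h,
#' 12-18 h, 18-24 h); one trained multiplier (knot) per period is anchored at
#' the period midpoint and smoothed by a periodic cubic spline, so the curve
#' is continuous and differentiable across midnight. Spline overshoot beyond
#' the multiplier bounds is clipped.
#'
#' @param parameters character vector of profiled parameter names (subset of
#'   [glycemia_param_names()]).
#' @param knots numeric vector (one profiled parameter) or matrix
#'   `length(parameters) x n_periods` of per-period multipliers.
#' @param n_periods number of equal-length day periods (default 4).
#' @param lower,upper clip bounds for the smoothed curve.
#' @return An object of class `"diurnal_profile"`.
#' @examples
#' pr <- diurnal_profile("kxi", c(0.7, 1.3, 1.0, 0.9))
#' profile_value(pr, c(180, 540, 900, 1260))   # the knots
#' @export
diurnal_profile <- function(parameters = "kxi", knots, n_periods = 4,
                            lower = 0.2, upper = 5) {
  stopifnot(all(parameters %in% glycemia_param_names()))
  knots <- matrix(knots, nrow = length(parameters))
  if (ncol(knots) != n_periods)
    stop("need one knot per period per parameter")
  edges <- seq(0, 1440, length.out = n_periods + 1)
  mids <- (edges[-1] + edges[-(n_periods + 1)]) / 2
  structure(list(parameters = parameters, knots = knots,
                 period_edges = edges, midpoints = mids,
                 lower = lower, upper = upper),
            class = "diurnal_profile")
}

#' @export
print.diurnal_profile <- function(x, ...) {
  cat("Diurnal profile (period 1440 min):\n")
  k <- x$knots; rownames(k) <- x$parameters
  colnames(k) <- sprintf("%02d:00-%02d:00", x$period_edges[-length(x$period_edges)] / 60,
                         x$period_edges[-1] / 60)
  print(round(k, 4))
  invisible(x)
}

#' Evaluate a diurnal profile
#'
#' Periodic cubic-spline evaluation of the multiplier curve at a clock
#' minute-of-day; continuous (and once differentiable) everywhere including
#' the midnight wrap, clipped to the profile bounds.
#'
#' @param profile a [diurnal_profile()].
#' @param minute_of_day minutes since midnight (vectorized; reduced mod
#'   1440).
#' @param parameter which profiled parameter to evaluate (default the
#'   first).
#' @return Multiplier values.
#' @export
profile_value <- function(profile, minute_of_day,
                          parameter = profile$parameters[1]) {
  stopifnot(inherits(profile, "diurnal_profile"))
  r <- match(parameter, profile$parameters)
  if (is.na(r)) stop("parameter not in profile")
  y <- profile$knots[r, ]
  if (all(abs(y - y[1]) < 1e-15)) return(rep(y[1], length(minute_of_day)))
  x <- profile$midpoints
  m <- ((minute_of_day - x[1]) %% 1440) + x[1]
  v <- spline(c(x, x[1] + 1440), c(y, y[1]), method = "periodic",
              xout = m)$y
  pmin(pmax(v, profile$lower), profile$upper)
}

# per-minute lookup table (rows = profiled parameters, 1441 columns so the
# compiled core can interpolate minute 1439 -> 1440 == minute 0)
profile_minute_table <- function(profile) {
  mins <- 0:1440
  t(vapply(profile$parameters,
           function(p) profile_value(profile, mins, p),
           numeric(1441)))
}

#' Train a diurnal parameter profile
#'
#' Per-period personalization of the profiled parameter(s): the configured
#' identification method is run once per day period (and swept over the
#' periods `sweeps` times, coordinate-descent style), each run minimizing
#' the RMSE over only the CGMS samples whose clock minute-of-day falls in
#' that period while the simulation always spans the whole window (digestion
#' and insulin dynamics cross period boundaries). Candidates are evaluated
#' through the actual smoothed profile -- the candidate knot is splined
#' together with the current estimates of the other periods' knots -- so the
#' cross-period memory of the insulin state does not bias the knots toward
#' each other. The final knots define the smoothed periodic profile.
#'
#' @inheritParams brute_force
#' @param space a [parameter_space()] over the profiled parameter(s),
#'   with `reference` set to the globally trained parameter values.
#' @param config a [training_config()]; stochastic methods are re-seeded
#'   per period run from `config$seed`.
#' @param refine_nm logical: refine each period's result by Nelder--Mead.
#' @param n_periods number of equal-length day periods.
#' @param sweeps coordinate-descent sweeps over the periods.
#' @return `list(profile, fit)`: the [diurnal_profile()] (multipliers
#'   relative to `space$reference`) and a `"fit_result"` whose fitness is the
#'   whole-log RMSE with the profile applied.
#' @export
train_diurnal <- function(log, space = parameter_space("kxi"),
                          config = training_config("ga_fast"),
                          refine_nm = TRUE, n_periods = 4, sweeps = 2,
                          absorption = absorption_params(), step = 1) {
  stopifnot(inherits(log, "patient_log"))
  if (log$duration < 1440) stop("diurnal training needs at least one full day")
  edges <- seq(0, 1440, length.out = n_periods + 1)
  cg <- log$measurements[log$measurements$source == "cgms", , drop = FALSE]
  mod <- (cg$time + log$start_minute_of_day) %% 1440
  nk <- length(space$names)
  knots <- matrix(1, nk, n_periods)
  n_eval <- 0L
  lo <- min(space$lower); hi <- max(space$upper)
  empty <- logical(n_periods)
  for (sw in seq_len(sweeps)) {
    for (p in seq_len(n_periods)) {
      mask <- mod >= edges[p] & mod < edges[p + 1]
      if (!any(mask)) {
        if (sw == 1) {
          warning("no CGMS samples in period ", p,
                  "; knot inherits the global trained value")
          empty[p] <- TRUE
        }
        next
      }
      objective <- function(m) {
        kk <- knots; kk[, p] <- m
        prof <- diurnal_profile(space$names, kk, n_periods, lo, hi)
        fitness(log, space$reference, prof, absorption, step, mask)
      }
      cfg <- config
      if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + (sw - 1L) * n_periods + p - 1L
      res <- switch(config$method,
        brute_force = brute_force(log, space, cfg, objective = objective),
        ga_fast = ,
        ga_slow = ga_optimize(log, space, cfg, objective = objective),
        nelder_mead_refine = nelder_mead_refine(log, space, knots[, p], cfg,
                                                objective = objective))
      if (refine_nm && config$method != "nelder_mead_refine") {
        res <- nelder_mead_refine(log, space, res,
                                  training_config("nelder_mead_refine"),
                                  objective = objective)
      }
      knots[, p] <- res$multipliers
      n_eval <- n_eval + res$n_eval
    }
  }
  prof <- diurnal_profile(space$names, knots, n_periods,
                          lower = min(space$lower), upper = max(space$upper))
  # report whole-log fitness of the reference parameters modulated by the
  # profile (the profile multiplies space$reference inside the simulator)
  total <- fitness(log, space$reference, prof, absorption, step)
  list(profile = prof,
       fit = fit_result(space, rep(1, length(space$names)), total, n_eval,
                        paste0("diurnal_", config$method)))
}
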