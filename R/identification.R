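#' Trainable parameter space
#'
#' Selects the subset of glycemia parameters to personalize, as dimensionless
#' multipliers of the reference (literature) values. The preset subsets follow
#' the model's sensitivity ranking: the 3 most influential parameters
#' (`kxgi`, `kxi`, `vi`), the 6 that matter (`+ tgh, vg, tigmax`), or all 9.
#' Multiplier bounds default to `[0.2, 5]`, wide but excluding clinically
#' impossible values.
#'
#' @param n_params 3, 6 or 9, or a character vector of parameter names.
#' @param lower,upper multiplier bounds (recycled per parameter); must
#'   bracket 1.
#' @param reference a [glycemia_params()] vector of reference values.
#' @return An object of class `"parameter_space"`.
#' @export
parameter_space <- function(n_params = 3, lower = 0.2, upper = 5,
                            reference = glycemia_params()) {
  presets <- list(
    `3` = c("kxgi", "kxi", "vi"),
    `6` = c("kxgi", "kxi", "vi", "tgh", "vg", "tigmax"),
    `9` = glycemia_param_names())
  names_ <- if (is.character(n_params)) n_params
            else presets[[as.character(n_params)]]
  if (is.null(names_) || !all(names_ %in% glycemia_param_names()))
    stop("n_params must be 3, 6, 9 or a vector of glycemia parameter names")
  k <- length(names_)
  lower <- rep_len(lower, k); upper <- rep_len(upper, k)
  if (any(lower >= 1) || any(upper <= 1))
    stop("multiplier bounds must contain 1.0")
  structure(list(names = names_, lower = lower, upper = upper,
                 reference = reference),
            class = "parameter_space")
}

#' Apply trained multipliers to the reference parameters
#'
#' @param space a [parameter_space()].
#' @param multipliers numeric vector, one per parameter in `space$names`.
#' @return A [glycemia_params()] vector with the selected entries scaled.
#' @export
apply_multipliers <- function(space, multipliers) {
  stopifnot(inherits(space, "parameter_space"),
            length(multipliers) == length(space$names))
  p <- space$reference
  p[space$names] <- p[space$names] * multipliers
  p
}

#' Training configuration presets
#'
#' Presets for the shipped identification methods. The genetic-algorithm
#' presets: *fast* uses population and generation number 10, crossover
#' probability 0.90 and mutation probability 0.01; *slow* uses population and
#' generation number 50, crossover probability 0.90 and mutation probability
#' 0.20. Brute force uses a 7-point additive multiplier grid with 20% step
#' size; Nelder--Mead refinement is capped at 100 iterations.
#'
#' @param method one of `"brute_force"`, `"ga_fast"`, `"ga_slow"`,
#'   `"nelder_mead_refine"`.
#' @param seed RNG seed for the stochastic methods.
#' @param ... overrides of individual preset fields (`pop_size`,
#'   `generations`, `p_crossover`, `p_mutation`, `mutation_sd`,
#'   `tournament_size`, `blend_alpha`, `elitism`, `steps`, `step_size`,
#'   `grid`, `max_iter`, `include_reference`).
#' @return A list of class `"training_config"`.
#' @export
training_config <- function(method = c("ga_slow", "ga_fast", "brute_force",
                                       "nelder_mead_refine"),
                            seed = NULL, ...) {
  method <- match.arg(method)
  base <- switch(method,
    brute_force = list(steps = 7, step_size = 0.20, grid = "additive"),
    ga_fast = list(pop_size = 10, generations = 10, p_crossover = 0.90,
                   p_mutation = 0.01),
    ga_slow = list(pop_size = 50, generations = 50, p_crossover = 0.90,
                   p_mutation = 0.20),
    nelder_mead_refine = list(max_iter = 100))
  if (method %in% c("ga_fast", "ga_slow"))
    base <- c(base, list(tournament_size = 3, blend_alpha = 0.5,
                         mutation_sd = 0.1, elitism = 1,
                         include_reference = TRUE))
  over <- list(...)
  unknown <- setdiff(names(over), c(names(base), "fitness"))
  if (length(unknown))
    stop("unknown training_config fields: ", paste(unknown, collapse = ", "))
  structure(c(list(method = method, seed = seed, fitness = "rmse"),
              modifyList(base, over)),
            class = "training_config")
}

#' Prediction fitness of a parameter vector on a log
#'
#' Simulates the full window (with restarts at every fingerstick) and returns
#' the RMSE against all CGMS readings, in mmol/l -- the figure of merit
#' minimized by all identification methods. A trajectory blow-up yields
#' `Inf` so the candidate is rejected rather than crashing the search.
#'
#' @inheritParams simulate_glucose
#' @param mask optional logical vector over the CGMS samples restricting the
#'   residuals entering the RMSE (used by diurnal per-period training; the
#'   simulation itself always spans the whole window).
#' @param ... further arguments (e.g. `g0`, `i0`) for [simulate_glucose()].
#' @return RMSE in mmol/l (`Inf` for unstable candidates).
#' @export
fitness <- function(log, params = glycemia_params(), profile = NULL,
                    absorption = absorption_params(), step = 1,
                    mask = NULL, ...) {
  cg <- log$measurements[log$measurements$source == "cgms", , drop = FALSE]
  if (!nrow(cg)) stop("fitness requires CGMS measurements")
  tr <- simulate_glucose(log, params, absorption, profile,
                         out_times = cg$time, step = step, restart = TRUE,
                         on_blowup = "na", ...)
  if (!isTRUE(attr(tr, "ok")) || anyNA(tr$G)) return(Inf)
  e <- tr$G - cg$value
  if (!is.null(mask)) e <- e[mask]
  if (!length(e)) return(Inf)
  sqrt(mean(e^2))
}

make_objective <- function(log, space, profile = NULL,
                           absorption = absorption_params(), step = 1,
                           mask = NULL) {
  force(log); force(space)
  function(m)
    fitness(log, apply_multipliers(space, m), profile, absorption, step, mask)
}

# wrap an objective with an evaluation counter
counted <- function(fun) {
  n <- 0L
  list(f = function(x) { n <<- n + 1L; fun(x) }, count = function() n)
}

fit_result <- function(space, multipliers, value, n_eval, method,
                       trace = NULL) {
  structure(list(space = space,
                 multipliers = setNames(multipliers, space$names),
                 params = apply_multipliers(space, multipliers),
                 fitness = value, n_eval = n_eval, method = method,
                 trace = trace),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s, RMSE %.4f mmol/l, %d evaluations>\n",
              x$method, x$fitness, x$n_eval))
  print(round(x$multipliers, 4))
  invisible(x)
}

#' One-factor-at-a-time sensitivity analysis
#'
#' Perturbs each trainable parameter in turn over a set of multipliers (all
#' others at their reference values) and records the prediction RMSE,
#' identifying the parameters with the largest effect on the model outcome.
#'
#' @inheritParams fitness
#' @param space a [parameter_space()].
#' @param multipliers multiplier levels; must include 1.
#' @return data.frame `(parameter, multiplier, fitness)`.
#' @export
ofat_sensitivity <- function(log, space = parameter_space(9),
                             multipliers = c(0.4, 0.6, 0.8, 1, 1.2, 1.4, 1.6),
                             profile = NULL,
                             absorption = absorption_params(), step = 1) {
  if (!any(abs(multipliers - 1) < 1e-12))
    stop("multipliers must include 1.0")
  base <- fitness(log, space$reference, profile, absorption, step)
  out <- expand.grid(parameter = space$names, multiplier = multipliers,
                     stringsAsFactors = FALSE)
  out$fitness <- vapply(seq_len(nrow(out)), function(r) {
    if (abs(out$multiplier[r] - 1) < 1e-12) return(base)
    m <- rep(1, length(space$names))
    m[match(out$parameter[r], space$names)] <- out$multiplier[r]
    fitness(log, apply_multipliers(space, m), profile, absorption, step)
  }, numeric(1))
  out[order(match(out$parameter, space$names), out$multiplier), ]
}

#' Brute-force grid identification
#'
#' Exhaustively evaluates a multiplier grid per trainable parameter. With the
#' default 7 steps of 20% size the additive grid is
#' `{0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6}` and the 3-parameter search costs
#' exactly `7^3 = 343` fitness evaluations.
#'
#' @inheritParams ofat_sensitivity
#' @param config a [training_config()] with method `"brute_force"`.
#' @return A `"fit_result"`.
#' @export
brute_force <- function(log, space = parameter_space(3),
                        config = training_config("brute_force"),
                        profile = NULL, absorption = absorption_params(),
                        step = 1, mask = NULL, objective = NULL) {
  steps <- config$steps
  if (steps %% 2 != 1) stop("steps must be odd so the grid contains 1.0")
  k <- (steps - 1) / 2
  levels_ <- if (identical(config$grid, "geometric"))
    (1 + config$step_size)^(-k:k) else 1 + (-k:k) * config$step_size
  obj <- counted(if (is.null(objective))
    make_objective(log, space, profile, absorption, step, mask)
  else objective)
  grid <- as.matrix(expand.grid(rep(list(levels_), length(space$names))))
  vals <- apply(grid, 1, obj$f)
  best <- which.min(vals)
  fit_result(space, unname(grid[best, ]), vals[best], obj$count(),
             "brute_force")
}

#' Genetic-algorithm identification
#'
#' Real-coded GA over multiplier vectors within the space bounds: tournament
#' selection, blend (BLX-alpha) crossover, per-gene Gaussian mutation,
#' elitism of 1, out-of-bound genes clipped. The best-ever individual is
#' returned; identical seeds give identical results.
#'
#' @inheritParams brute_force
#' @param config a [training_config()] with a GA preset (`"ga_slow"`
#'   default, or `"ga_fast"`).
#' @return A `"fit_result"` whose `trace` holds the best fitness per
#'   generation.
#' @export
ga_optimize <- function(log, space = parameter_space(3),
                        config = training_config("ga_slow"),
                        profile = NULL, absorption = absorption_params(),
                        step = 1, mask = NULL, objective = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  obj <- counted(if (is.null(objective))
    make_objective(log, space, profile, absorption, step, mask)
  else objective)
  k <- length(space$names)
  lo <- space$lower; hi <- space$upper
  clip <- function(m) pmin(pmax(m, lo), hi)
  np <- config$pop_size
  pop <- matrix(runif(np * k), np, k)
  pop <- sweep(sweep(pop, 2, hi - lo, "*"), 2, lo, "+")
  if (isTRUE(config$include_reference)) pop[1, ] <- 1
  fit <- apply(pop, 1, obj$f)
  best_m <- pop[which.min(fit), ]; best_v <- min(fit)
  trace <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    sel <- function() {
      cand <- sample.int(np, config$tournament_size, replace = TRUE)
      cand[which.min(fit[cand])]
    }
    newpop <- matrix(NA_real_, np, k)
    for (j in seq(1, np, by = 2)) {
      p1 <- pop[sel(), ]; p2 <- pop[sel(), ]
      if (runif(1) < config$p_crossover) {
        a <- config$blend_alpha
        lo_g <- pmin(p1, p2) - a * abs(p1 - p2)
        hi_g <- pmax(p1, p2) + a * abs(p1 - p2)
        c1 <- runif(k, lo_g, hi_g); c2 <- runif(k, lo_g, hi_g)
      } else { c1 <- p1; c2 <- p2 }
      newpop[j, ] <- c1
      if (j + 1 <= np) newpop[j + 1, ] <- c2
    }
    mut <- matrix(runif(np * k) < config$p_mutation, np, k)
    newpop <- newpop + mut * matrix(rnorm(np * k, 0, config$mutation_sd), np, k)
    newpop <- pmin(pmax(newpop, matrix(lo, np, k, byrow = TRUE)),
                   matrix(hi, np, k, byrow = TRUE))
    if (config$elitism > 0) newpop[1, ] <- best_m  # keep best-ever
    pop <- newpop
    fit <- apply(pop, 1, obj$f)
    if (min(fit) < best_v) { best_v <- min(fit); best_m <- pop[which.min(fit), ] }
    trace[gen] <- best_v
  }
  fit_result(space, unname(best_m), best_v, obj$count(),
             config$method, trace)
}

#' Nelder--Mead simplex refinement
#'
#' Downhill-simplex minimization of the same fitness starting from a trained
#' multiplier vector, with the initial simplex spanned by +5% perturbations
#' of the start along each coordinate. Vertices are clipped to the space
#' bounds; on simplex collapse the current best vertex is returned. The
#' result never has worse fitness than the start.
#'
#' @inheritParams brute_force
#' @param start a `"fit_result"` (typically from [ga_optimize()]) or a
#'   numeric multiplier vector.
#' @param config a [training_config()] with method `"nelder_mead_refine"`.
#' @param objective optional objective `function(multipliers)`; defaults to
#'   the prediction fitness on `log` (exposed for testing on surrogates).
#' @return A `"fit_result"`.
#' @export
nelder_mead_refine <- function(log = NULL, space = parameter_space(3),
                               start,
                               config = training_config("nelder_mead_refine"),
                               profile = NULL,
                               absorption = absorption_params(), step = 1,
                               mask = NULL, objective = NULL) {
  x0 <- if (inherits(start, "fit_result")) unname(start$multipliers)
        else as.numeric(start)
  k <- length(space$names)
  stopifnot(length(x0) == k)
  clip <- function(m) pmin(pmax(m, space$lower), space$upper)
  obj <- if (is.null(objective))
    make_objective(log, space, profile, absorption, step, mask)
  else objective
  n_eval <- 0L
  f <- function(x) { n_eval <<- n_eval + 1L; obj(clip(x)) }

  # initial simplex: start plus +5% perturbation along each coordinate
  simplex <- matrix(rep(x0, k + 1), nrow = k + 1, byrow = TRUE)
  for (j in seq_len(k))
    simplex[j + 1, j] <- x0[j] * 1.05 + (x0[j] == 0) * 0.05
  vals <- apply(simplex, 1, f)
  alpha <- 1; gamma_e <- 2; rho <- 0.5; sigma <- 0.5
  for (it in seq_len(config$max_iter)) {
    ord <- order(vals); simplex <- simplex[ord, , drop = FALSE]; vals <- vals[ord]
    if (max(apply(simplex, 2, function(c) diff(range(c)))) < 1e-10 ||
        (is.finite(vals[k + 1]) && vals[k + 1] - vals[1] < 1e-12))
      break  # simplex collapse
    centroid <- colMeans(simplex[1:k, , drop = FALSE])
    xr <- centroid + alpha * (centroid - simplex[k + 1, ])
    fr <- f(xr)
    if (fr < vals[1]) {
      xe <- centroid + gamma_e * (xr - centroid)
      fe <- f(xe)
      if (fe < fr) { simplex[k + 1, ] <- xe; vals[k + 1] <- fe }
      else { simplex[k + 1, ] <- xr; vals[k + 1] <- fr }
    } else if (fr < vals[k]) {
      simplex[k + 1, ] <- xr; vals[k + 1] <- fr
    } else {
      xc <- centroid + rho * (simplex[k + 1, ] - centroid)
      fc <- f(xc)
      if (fc < vals[k + 1]) { simplex[k + 1, ] <- xc; vals[k + 1] <- fc }
      else {
        for (j in 2:(k + 1)) {
          simplex[j, ] <- simplex[1, ] + sigma * (simplex[j, ] - simplex[1, ])
          vals[j] <- f(simplex[j, ])
        }
      }
    }
  }
  best <- which.min(vals)
  xb <- clip(simplex[best, ]); vb <- vals[best]
  # monotone-improvement contract against the supplied start
  v0 <- if (inherits(start, "fit_result")) start$fitness else f(x0)
  if (v0 < vb) { xb <- clip(x0); vb <- v0 }
  fit_result(space, unname(xb), vb, n_eval, "nelder_mead_refine")
}
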