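#' CGMS and fingerstick noise specification
#'
#' The CGMS error model is multiplicative white Gaussian noise plus a slowly
#' varying AR(1) drift whose amplitude grows linearly with sensor age
#' (sensors degrade over their six-day lifetime). The shipped defaults are
#' calibrated so that, on typical virtual-patient traces, the median absolute
#' difference from truth is about 1.4 mmol/l and the mean relative
#' difference about 17%, matching clinical CGMS error reports in outpatient
#' care. Fingerstick meters get small independent relative noise.
#'
#' @param relative_sd sd of the white multiplicative error (dimensionless).
#' @param drift_sd stationary sd of the drift at sensor age 0.
#' @param drift_tau drift correlation time, min.
#' @param drift_age_growth linear growth of drift sd per sensor day.
#' @param sensor_life_days sensor replacement interval, days.
#' @param fingerstick_cv coefficient of variation of fingerstick readings.
#' @return A list of class `"cgms_noise_spec"`.
#' @export
cgms_noise_spec <- function(relative_sd = 0.15, drift_sd = 0.13,
                            drift_tau = 240, drift_age_growth = 0.15,
                            sensor_life_days = 6, fingerstick_cv = 0.05) {
  spec <- list(relative_sd = relative_sd, drift_sd = drift_sd,
               drift_tau = drift_tau, drift_age_growth = drift_age_growth,
               sensor_life_days = sensor_life_days,
               fingerstick_cv = fingerstick_cv)
  if (any(unlist(spec) < 0)) stop("noise parameters must be >= 0")
  structure(spec, class = "cgms_noise_spec")
}

#' Noise-free measurement spec
#' @return A [cgms_noise_spec()] with every noise source zero.
#' @export
noise_free <- function() {
  cgms_noise_spec(relative_sd = 0, drift_sd = 0, drift_age_growth = 0,
                  fingerstick_cv = 0)
}

# small built-in food table: decomposed nutrient content per meal slot (g)
food_table <- function() {
  data.frame(
    slot = c("breakfast", "lunch", "dinner", "snack"),
    mono_g = c(15, 10, 10, 20),
    starch_g = c(40, 60, 45, 10),
    gi = c(0.9, 0.8, 0.7, 1.0),
    lipid_g = c(10, 20, 15, 5),
    protein_g = c(15, 30, 25, 5),
    fiber_g = c(4, 8, 6, 2),
    stringsAsFactors = FALSE)
}

#' Virtual patient specification
#'
#' Describes one synthetic patient: the true model parameters (multipliers of
#' the literature reference values), an optional planted diurnal insulin
#' sensitivity pattern, body weight, the daily meal/insulin schedule, and
#' the measurement noise model.
#'
#' @param multipliers named numeric vector of true parameter multipliers
#'   (subset of [glycemia_param_names()]; unnamed parameters stay at 1).
#' @param diurnal_knots optional vector of 4 per-period multipliers planted
#'   on `kxi` (smoothed into a periodic profile before simulating truth).
#' @param body_weight_kg body weight.
#' @param meal_times_min clock minutes of the main meals.
#' @param meal_slots food-table slots matching `meal_times_min`.
#' @param meal_time_jitter_sd sd of the meal-time jitter, min.
#' @param meal_size_jitter_sdlog lognormal sd of the meal-size factor.
#' @param iu_per_10g_carb bolus dosing rule, IU per 10 g carbohydrate.
#' @param bolus_jitter relative half-width of the dosing imperfection (the
#'   patient doses by experience, so boluses are deliberately off by up to
#'   this fraction).
#' @param bolus_product,basal_product product ids from [insulin_products()].
#' @param basal_dose_iu,basal_time_min once-daily basal dose and clock time.
#' @param noise a [cgms_noise_spec()].
#' @return A list of class `"virtual_patient_spec"`.
#' @export
virtual_patient_spec <- function(multipliers = c(kxgi = 1, kxi = 1, vi = 1),
                                 diurnal_knots = NULL,
                                 body_weight_kg = 80,
                                 meal_times_min = c(450, 750, 1110),
                                 meal_slots = c("breakfast", "lunch", "dinner"),
                                 meal_time_jitter_sd = 15,
                                 meal_size_jitter_sdlog = 0.15,
                                 iu_per_10g_carb = 0.5,
                                 bolus_jitter = 0.2,
                                 bolus_product = "rapid",
                                 basal_dose_iu = 4,
                                 basal_time_min = 1350,
                                 basal_product = "long",
                                 noise = cgms_noise_spec()) {
  stopifnot(all(names(multipliers) %in% glycemia_param_names()),
            length(meal_times_min) == length(meal_slots),
            all(meal_slots %in% food_table()$slot))
  if (any(meal_times_min < 0 | meal_times_min >= 1440) ||
      basal_time_min < 0 || basal_time_min >= 1440)
    stop("scheduled times must lie within the day")
  structure(as.list(environment()), class = "virtual_patient_spec")
}

#' Sample a virtual patient from a population template
#'
#' Draws the true multipliers of the trainable parameters from a log-normal
#' distribution with median 1 (so half the population sits on either side of
#' the literature value), truncated to the identification bounds.
#'
#' @param template a [virtual_patient_spec()] providing everything except
#'   the multipliers.
#' @param seed RNG seed.
#' @param sdlog log-scale sd of the multiplier distribution.
#' @param space a [parameter_space()] naming the sampled parameters and
#'   their bounds.
#' @return A [virtual_patient_spec()] with sampled `multipliers`.
#' @export
sample_patient <- function(template = virtual_patient_spec(), seed = NULL,
                           sdlog = 0.2, space = parameter_space(3)) {
  if (!is.null(seed)) set.seed(seed)
  m <- rlnorm(length(space$names), 0, sdlog)
  m <- pmin(pmax(m, space$lower), space$upper)
  template$multipliers <- setNames(m, space$names)
  template
}

#' Generate a virtual-patient lifestyle log
#'
#' Builds a multi-day meal/insulin schedule from the spec (main meals with
#' jittered times and sizes, a carbohydrate-proportional but deliberately
#' imperfect bolus before each meal, once-daily basal insulin at bedtime,
#' a fingerstick before each main meal), simulates the true model with the
#' planted parameters (and planted diurnal profile, if any), and emits CGMS
#' readings at 5-minute cadence through the noise model. Ground truth is
#' returned separately; the whole generation is deterministic under `seed`.
#'
#' @param spec a [virtual_patient_spec()].
#' @param days number of days (>= 1).
#' @param seed RNG seed.
#' @param step integration step for the truth simulation, min.
#' @return List with elements `log` (a [patient_log()]), `truth`
#'   (data.frame `t, G, I` at CGMS times), `params` (true absolute
#'   [glycemia_params()]), `profile` (planted [diurnal_profile()] or NULL)
#'   and `spec`.
#' @examples
#' vp <- generate_virtual_patient(days = 3, seed = 7)
#' vp$log
#' @export
generate_virtual_patient <- function(spec = virtual_patient_spec(), days = 3,
                                     seed = NULL, step = 1) {
  stopifnot(inherits(spec, "virtual_patient_spec"), days >= 1)
  if (!is.null(seed)) set.seed(seed)
  ft <- food_table()
  meals <- list(); insulins <- list(); fs_times <- numeric(0)
  for (d in seq_len(days) - 1) {
    jit <- round(pmin(pmax(rnorm(length(spec$meal_times_min), 0,
                                 spec$meal_time_jitter_sd), -45), 45))
    times <- d * 1440 + spec$meal_times_min + jit
    for (k in seq_along(times)) {
      row <- ft[ft$slot == spec$meal_slots[k], ]
      size <- rlnorm(1, 0, spec$meal_size_jitter_sdlog)
      meals[[length(meals) + 1]] <- meal_event(
        times[k], mono_g = row$mono_g * size, starch_g = row$starch_g * size,
        gi = row$gi, lipid_g = row$lipid_g * size,
        protein_g = row$protein_g * size, fiber_g = row$fiber_g * size)
      carbs <- (row$mono_g + row$starch_g) * size
      dose <- max(0.5, round(2 * carbs / 10 * spec$iu_per_10g_carb *
                               runif(1, 1 - spec$bolus_jitter,
                                     1 + spec$bolus_jitter)) / 2)
      insulins[[length(insulins) + 1]] <-
        insulin_event(times[k], dose, product = spec$bolus_product)
      fs_times <- c(fs_times, times[k])
    }
    insulins[[length(insulins) + 1]] <-
      insulin_event(d * 1440 + spec$basal_time_min, spec$basal_dose_iu,
                    product = spec$basal_product)
  }
  meals <- do.call(rbind, meals)
  insulins <- do.call(rbind, insulins)
  meals <- meals[order(meals$time), ]
  insulins <- insulins[order(insulins$time), ]

  params <- glycemia_params()
  params[names(spec$multipliers)] <-
    params[names(spec$multipliers)] * spec$multipliers
  profile <- if (!is.null(spec$diurnal_knots))
    diurnal_profile("kxi", spec$diurnal_knots) else NULL

  cg_times <- seq(0, days * 1440 - 5, by = 5)
  duration <- days * 1440
  skeleton <- patient_log("virtual", spec$body_weight_kg, meals, insulins,
                          duration = duration)
  out_t <- sort(unique(c(cg_times, fs_times)))
  tr <- simulate_glucose(skeleton, params, profile = profile,
                         out_times = out_t, step = step, restart = FALSE)
  g_at <- function(tt) tr$G[match(tt, tr$t)]

  ns <- spec$noise
  g_cg <- g_at(cg_times)
  n <- length(cg_times)
  white <- rnorm(n, 0, ns$relative_sd)
  drift <- numeric(n)
  if (ns$drift_sd > 0) {
    rho <- exp(-5 / ns$drift_tau)
    sens_day <- floor(cg_times / 1440) %% ns$sensor_life_days
    sdk <- ns$drift_sd * (1 + ns$drift_age_growth * sens_day)
    drift[1] <- rnorm(1, 0, sdk[1])
    for (k in 2:n)
      drift[k] <- rho * drift[k - 1] + sqrt(1 - rho^2) * rnorm(1, 0, sdk[k])
  }
  cg_val <- pmax(g_cg * (1 + white + drift), 0.5)
  fs_val <- pmax(g_at(fs_times) *
                   (1 + rnorm(length(fs_times), 0, ns$fingerstick_cv)), 0.5)

  meas <- rbind(
    data.frame(time = cg_times, value = cg_val, source = "cgms",
               stringsAsFactors = FALSE),
    data.frame(time = fs_times, value = fs_val, source = "fingerstick",
               stringsAsFactors = FALSE))
  meas <- meas[order(meas$time, meas$source), ]

  log <- patient_log("virtual", spec$body_weight_kg, meals, insulins, meas,
                     duration = duration)
  list(log = log,
       truth = data.frame(t = cg_times, G = g_cg,
                          I = tr$I[match(cg_times, tr$t)]),
       params = params, profile = profile, spec = spec)
}
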