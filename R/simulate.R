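#' Simulate the coupled digestion + glucose-insulin model over a log
#'
#' Co-integrates the two-compartment digestion model and the
#' delay-differential glucose control model on one fixed-step RK4 clock
#' (compiled core). Meals and injections are applied as impulses at their
#' timestamps; the pancreatic delay uses a linearly interpolated per-step
#' glucose history; with `restart = TRUE` the model glucose is reset to every
#' fingerstick value (insulin and depots untouched) as it would be in a
#' lifestyle-support deployment.
#'
#' @param log a [patient_log()].
#' @param params a [glycemia_params()] vector.
#' @param absorption an [absorption_params()] vector.
#' @param profile optional [diurnal_profile()] multiplying selected
#'   parameters by a periodic minute-of-day curve.
#' @param out_times sampling times, min; default all CGMS timestamps, or a
#'   5-min grid when the log has none.
#' @param horizon simulation end, min (default log duration).
#' @param step integration step, min (default 1; must not exceed `tau_g`).
#' @param restart logical: restart at fingerstick measurements.
#' @param g0,i0 initial glucose / insulin; defaults: the first logged
#'   measurement value (else basal steady-state G) and steady-state I.
#' @param on_blowup `"error"` aborts on a non-finite trajectory naming the
#'   parameter vector; `"na"` returns the partial trajectory with attribute
#'   `ok = FALSE` (used to reject candidates during training).
#' @return data.frame `(t, G, I)` of class `"glucose_trajectory"` with
#'   attributes `ok` and `balance` (compartment mass bookkeeping).
#' @examples
#' log <- generate_virtual_patient(days = 1, seed = 1)$log
#' tr <- simulate_glucose(log)
#' head(tr)
#' @export
simulate_glucose <- function(log, params = glycemia_params(),
                             absorption = absorption_params(),
                             profile = NULL, out_times = NULL,
                             horizon = NULL, step = 1, restart = TRUE,
                             g0 = NULL, i0 = NULL,
                             on_blowup = c("error", "na")) {
  stopifnot(inherits(log, "patient_log"))
  on_blowup <- match.arg(on_blowup)
  if (is.null(horizon)) horizon <- log$duration
  if (is.null(out_times)) {
    out_times <- log$measurements$time[log$measurements$source == "cgms"]
    if (!length(out_times)) out_times <- seq(0, horizon, by = 5)
  }
  out_times <- out_times[out_times <= horizon + 1e-9]
  if (is.null(g0) || is.null(i0)) {
    ss <- steady_state(params)
    if (is.null(i0)) i0 <- ss[["I"]]
    if (is.null(g0)) {
      g0 <- if (nrow(log$measurements)) log$measurements$value[1] else ss[["G"]]
    }
  }

  me <- log$meals[log$meals$time <= horizon, , drop = FALSE]
  st <- me[me$starch_g > 0, , drop = FALSE]
  ins <- log$insulins[log$insulins$time <= horizon, , drop = FALSE]
  fs <- log$measurements[log$measurements$source == "fingerstick" &
                           log$measurements$time <= horizon, , drop = FALSE]
  if (!restart) fs <- fs[0, , drop = FALSE]

  if (is.null(profile)) {
    prof_tab <- matrix(numeric(0), nrow = 0, ncol = 1441)
    prof_par <- integer(0)
  } else {
    stopifnot(inherits(profile, "diurnal_profile"))
    prof_tab <- profile_minute_table(profile)
    prof_par <- match(profile$parameters, glycemia_param_names()) - 1L
    if (anyNA(prof_par)) stop("unknown profiled parameter")
  }

  res <- sim_core(
    me$time, me$mono_g, me$lipid_g, me$protein_g, me$fiber_g,
    st$time, st$starch_g, st$gi,
    ins$time, ins$dose_iu * 6000 / log$body_weight_kg, ins$t_max_I,
    fs$time, fs$value,
    out_times,
    as.numeric(params), log$body_weight_kg, as.numeric(absorption),
    g0, i0, horizon, step,
    prof_tab, prof_par, log$start_minute_of_day)

  if (!res$ok && on_blowup == "error")
    stop("trajectory blow-up (non-finite or out-of-range G/I) for parameters: ",
         paste(sprintf("%s=%.4g", names(params), as.numeric(params)),
               collapse = ", "))
  ingested <- sum(me$mono_g) + sum(st$starch_g)
  out <- data.frame(t = out_times, G = res$G, I = res$I)
  structure(out, class = c("glucose_trajectory", "data.frame"),
            ok = res$ok,
            balance = list(
              ingested_g = ingested,
              stomach_g = res$stomach_digestible_g,
              intestine_g = res$intestine_digestible_g,
              absorbed_g = res$cum_absorbed_g,
              insulin_injected_pmol_kg =
                sum(ins$dose_iu) * 6000 / log$body_weight_kg,
              insulin_depot_pmol_kg = res$depot_residual_pmol_kg,
              insulin_appeared_pmol_kg = res$cum_insulin_appearance_pmol_kg))
}

#' @export
print.glucose_trajectory <- function(x, ...) {
  cat(sprintf("Glucose trajectory: %d samples over %.1f h, G in [%.2f, %.2f] mmol/l\n",
              nrow(x), diff(range(x$t)) / 60, min(x$G), max(x$G)))
  invisible(x)
}
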