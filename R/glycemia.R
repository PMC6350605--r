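#' Glycemia model state and derivatives (reference implementation)
#'
#' The glucose control model couples plasma glucose G (mmol/l) and plasma
#' insulin I (pM) with per-administration subcutaneous depot pairs (S1, S2,
#' pmol/kgBW):
#' \deqn{dG/dt = -K_{xgi} G I + T_{GH}/V_G + \Delta a_{Monosac}(t)}
#' \deqn{dI/dt = -K_{xi} I + (T_{iGmax}/V_I) f(G(t - \tau_G)) +
#'   \sum_d S2_d/(V_I t_{max,I,d})}
#' \deqn{dS1_d/dt = -S1_d/t_{max,I,d}, \quad dS2_d/dt = (S1_d - S2_d)/t_{max,I,d}}
#' where an injection adds its dose to S1 of a new depot pair and
#' \eqn{f} is [endogenous_release_fraction()] evaluated at glucose delayed by
#' `tau_g` minutes. These R functions document and unit-test the equations;
#' whole-log integration uses the compiled core in [simulate_glucose()].
#'
#' @param t time, min.
#' @param g glucose, mmol/l.
#' @param i insulin, pM.
#' @param depots data.frame with columns `s1`, `s2` (pmol/kgBW), `t_max_I`
#'   (min), one row per administration.
#' @return `model_state()` returns a `"model_state"` list.
#' @export
model_state <- function(t = 0, g, i, depots = empty_depots()) {
  stopifnot(g > 0, i >= 0, all(depots$s1 >= 0), all(depots$s2 >= 0))
  structure(list(t = t, g = g, i = i, depots = depots), class = "model_state")
}

empty_depots <- function() {
  data.frame(s1 = numeric(0), s2 = numeric(0), t_max_I = numeric(0))
}

#' @rdname model_state
#' @param state a `"model_state"`.
#' @param event one row of an insulin event data.frame ([insulin_event()]);
#'   its time must equal the state time.
#' @param body_weight_kg body weight, kg.
#' @return `inject_insulin()` returns the state with a new depot pair whose
#'   S1 holds `dose_iu * 6000 / body_weight_kg` pmol/kgBW (1 IU = 6 nmol).
#' @export
inject_insulin <- function(state, event, body_weight_kg) {
  stopifnot(inherits(state, "model_state"))
  if (event$dose_iu <= 0) stop("insulin dose must be > 0")
  if (abs(event$time - state$t) > 1e-9)
    stop("injection time must equal the state time")
  state$depots <- rbind(state$depots,
                        data.frame(s1 = event$dose_iu * 6000 / body_weight_kg,
                                   s2 = 0, t_max_I = event$t_max_I))
  state
}

#' @rdname model_state
#' @param params a [glycemia_params()] vector.
#' @param delta_a_monosac glucose appearance, mmol/l/min.
#' @param g_delayed glucose at `t - tau_g`, mmol/l (supplied by the caller's
#'   history buffer).
#' @return `glycemia_deriv()` returns `list(dg, di, ddepots)`.
#' @export
glycemia_deriv <- function(state, params = glycemia_params(),
                           delta_a_monosac = 0, g_delayed) {
  stopifnot(inherits(state, "model_state"))
  if (missing(g_delayed)) stop("delayed glucose history is required")
  p <- params
  f <- endogenous_release_fraction(max(g_delayed, 0), p[["g_star"]],
                                   p[["gamma"]])
  dep_in <- if (nrow(state$depots))
    sum(state$depots$s2 / (p[["vi"]] * state$depots$t_max_I)) else 0
  list(
    dg = -p[["kxgi"]] * state$g * state$i + p[["tgh"]] / p[["vg"]] +
      delta_a_monosac,
    di = -p[["kxi"]] * state$i + (p[["tigmax"]] / p[["vi"]]) * f + dep_in,
    ddepots = data.frame(
      s1 = -state$depots$s1 / state$depots$t_max_I,
      s2 = (state$depots$s1 - state$depots$s2) / state$depots$t_max_I))
}

#' Restart the model at a fingerstick measurement
#'
#' Sets the current glucose to the measured value and re-seeds the delayed
#' glucose history, leaving insulin and all depot states untouched, so that
#' digestion and insulin evolution overlapping the measurement are preserved.
#'
#' @param state a `"model_state"`.
#' @param measurement one row of a measurement data.frame with
#'   `source == "fingerstick"` and `time` equal to the state time.
#' @return The restarted state.
#' @export
restart_state <- function(state, measurement) {
  stopifnot(inherits(state, "model_state"))
  if (measurement$source != "fingerstick")
    stop("restart requires a fingerstick measurement")
  if (abs(measurement$time - state$t) > 1e-9)
    stop("measurement time must equal the state time")
  if (measurement$value <= 0) stop("measurement must be positive")
  state$g <- measurement$value
  state
}
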