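#' Two-compartment digestion model: state and derivatives
#'
#' The digestion model tracks five nutrient classes in the stomach
#' (free monosaccharides, starch portions with individual glycemic indices,
#' lipids, proteins, fibers) and digestible carbohydrate in the intestine.
#' Gastric emptying is first order with a rate retarded by the lipid, protein
#' and fiber mass currently in the stomach; starch is hydrolyzed to
#' monosaccharide in the intestine at a rate proportional to its glycemic
#' index; free intestinal monosaccharide is absorbed at rate `kabs`, and the
#' absorbed flux is the glucose appearance rate that drives the glycemia
#' model. All mass balances are linear, so overlapping meals superpose.
#'
#' `absorption_state()` builds an empty state; `add_meal()` adds a meal's
#' masses to the stomach (an impulse; the intestine is untouched);
#' `absorption_deriv()` returns the time derivative of every compartment and
#' the monosaccharide appearance rate in g/min.
#'
#' @param state an `"absorption_state"` list.
#' @param meal a one-row data.frame from [meal_event()] (or several rows).
#' @param params an [absorption_params()] vector.
#' @return `absorption_state()` and `add_meal()` return the state;
#'   `absorption_deriv()` returns `list(d, appearance_g_min)` where `d`
#'   mirrors the state layout.
#' @export
absorption_state <- function() {
  structure(list(mono = 0, lipid = 0, protein = 0, fiber = 0,
                 starch = data.frame(stomach_g = numeric(0),
                                     intestine_g = numeric(0),
                                     gi = numeric(0)),
                 intestine_mono = 0, cum_absorbed = 0),
            class = "absorption_state")
}

#' @rdname absorption_state
#' @export
add_meal <- function(state, meal) {
  stopifnot(inherits(state, "absorption_state"))
  for (k in seq_len(nrow(meal))) {
    m <- meal[k, ]
    if (any(c(m$mono_g, m$starch_g, m$lipid_g, m$protein_g, m$fiber_g) < 0))
      stop("meal masses must be non-negative")
    state$mono <- state$mono + m$mono_g
    state$lipid <- state$lipid + m$lipid_g
    state$protein <- state$protein + m$protein_g
    state$fiber <- state$fiber + m$fiber_g
    if (m$starch_g > 0)
      state$starch <- rbind(state$starch,
                            data.frame(stomach_g = m$starch_g,
                                       intestine_g = 0, gi = m$gi))
  }
  state
}

#' @rdname absorption_state
#' @export
absorption_deriv <- function(state, params = absorption_params()) {
  stopifnot(inherits(state, "absorption_state"))
  masses <- c(state$mono, state$lipid, state$protein, state$fiber,
              state$starch$stomach_g, state$starch$intestine_g,
              state$intestine_mono)
  if (any(masses < -1e-9)) stop("negative compartment mass (integrator fault)")
  p <- params
  retard <- 1 + p[["c_lipid"]] * state$lipid +
    p[["c_protein"]] * state$protein + p[["c_fiber"]] * state$fiber
  kemp <- p[["kge"]] / retard
  hyd <- p[["khyd_ref"]] * state$starch$gi * state$starch$intestine_g
  appearance <- p[["kabs"]] * state$intestine_mono
  d <- list(
    mono = -kemp * state$mono,
    lipid = -kemp * state$lipid,
    protein = -kemp * state$protein,
    fiber = -kemp * state$fiber,
    starch = data.frame(
      stomach_g = -kemp * state$starch$stomach_g,
      intestine_g = kemp * state$starch$stomach_g - hyd,
      gi = state$starch$gi),
    intestine_mono = kemp * state$mono + sum(hyd) - appearance,
    cum_absorbed = appearance)
  list(d = d, appearance_g_min = appearance)
}

#' Glucose appearance as a concentration rate
#'
#' Converts the intestinal monosaccharide absorption rate (g/min) into the
#' rate of change of glucose concentration in the glucose distribution
#' volume: `appearance / 180.16 * 1000 / (vg * body_weight)` mmol/l/min.
#'
#' @param appearance_g_min absorption rate, g/min (>= 0).
#' @param vg glucose distribution volume, l/kgBW.
#' @param body_weight_kg body weight, kg.
#' @return Concentration rate, mmol/l/min.
#' @export
glucose_input_rate <- function(appearance_g_min, vg = 0.187, body_weight_kg) {
  if (any(appearance_g_min < 0)) stop("appearance rate must be >= 0")
  if (vg <= 0 || body_weight_kg <= 0)
    stop("vg and body weight must be positive")
  appearance_g_min / 180.16 * 1000 / (vg * body_weight_kg)
}
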