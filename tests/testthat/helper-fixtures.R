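# shared fixtures: small logs and scenarios built in code

# one meal + one rapid bolus, 6 h; used by integrator-equivalence checks
six_hour_scenario <- function(body_weight = 80) {
  patient_log(
    patient_id = "scenario",
    body_weight_kg = body_weight,
    meals = meal_event(30, mono_g = 30, starch_g = 40, gi = 0.9,
                       lipid_g = 15, protein_g = 20, fiber_g = 5),
    insulins = insulin_event(30, 5, product = "rapid"),
    duration = 360)
}

# noise-free virtual patient cached per (multipliers, days, seed)
nf_patient <- local({
  cache <- list()
  function(multipliers = c(kxgi = 1, kxi = 1, vi = 1), days = 3, seed = 11,
           diurnal_knots = NULL) {
    key <- paste(c(multipliers, days, seed, diurnal_knots), collapse = "_")
    if (is.null(cache[[key]])) {
      spec <- virtual_patient_spec(multipliers = multipliers,
                                   diurnal_knots = diurnal_knots,
                                   noise = noise_free())
      cache[[key]] <<- generate_virtual_patient(spec, days = days, seed = seed)
    }
    cache[[key]]
  }
})

# a log whose CGMS equals the model's own output for `params` (no
# fingersticks), so the prediction fitness has an exact zero
self_consistent_log <- function(params = glycemia_params(), days = 1,
                                seed = 31, offset = 0) {
  vp <- generate_virtual_patient(
    virtual_patient_spec(noise = noise_free()), days = days, seed = seed)
  skel <- vp$log
  cg_t <- seq(0, days * 1440 - 5, by = 5)
  ss <- steady_state(params)
  tr <- simulate_glucose(skel, params, out_times = cg_t, restart = FALSE,
                         g0 = ss[["G"]], i0 = ss[["I"]])
  patient_log("selfcons", skel$body_weight_kg, skel$meals, skel$insulins,
              data.frame(time = cg_t, value = tr$G + offset, source = "cgms",
                         stringsAsFactors = FALSE),
              duration = skel$duration)
}
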