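# small forward-Euler driver for the R-level digestion derivatives, used to
# probe the absorption model in isolation
integrate_absorption <- function(state, params, horizon, dt = 0.1) {
  times <- seq(0, horizon, by = dt)
  appear <- numeric(length(times))
  for (k in seq_along(times)) {
    d <- absorption_deriv(state, params)
    appear[k] <- d$appearance_g_min
    state$mono <- state$mono + dt * d$d$mono
    state$lipid <- state$lipid + dt * d$d$lipid
    state$protein <- state$protein + dt * d$d$protein
    state$fiber <- state$fiber + dt * d$d$fiber
    state$starch$stomach_g <- state$starch$stomach_g + dt * d$d$starch$stomach_g
    state$starch$intestine_g <- state$starch$intestine_g + dt * d$d$starch$intestine_g
    state$intestine_mono <- state$intestine_mono + dt * d$d$intestine_mono
    state$cum_absorbed <- state$cum_absorbed + dt * d$d$cum_absorbed
  }
  list(times = times, appearance = appear, state = state)
}

test_that("meals add mass to the stomach additively and support overlap", {
  s <- absorption_state()
  s1 <- add_meal(s, meal_event(0, mono_g = 10))
  expect_equal(s1$mono, 10)
  expect_equal(s1$intestine_mono, 0)

  a <- meal_event(0, mono_g = 3, starch_g = 20, gi = 0.8, lipid_g = 5)
  b <- meal_event(0, mono_g = 7, protein_g = 10)
  one_by_one <- add_meal(add_meal(s, a), b)
  expect_equal(one_by_one$mono, 10)
  expect_equal(one_by_one$lipid, 5)
  expect_equal(one_by_one$protein, 10)
  expect_equal(sum(one_by_one$starch$stomach_g), 20)

  # residual mass superposes with a new meal
  s2 <- add_meal(s, meal_event(0, mono_g = 5))
  s2 <- add_meal(s2, meal_event(0, mono_g = 10))
  expect_equal(s2$mono, 15)

  expect_error(add_meal(s, data.frame(time = 0, mono_g = -1, starch_g = 0,
                                      gi = 1, lipid_g = 0, protein_g = 0,
                                      fiber_g = 0)),
               "non-negative")
})

test_that("empty state has zero derivatives and appearance", {
  d <- absorption_deriv(absorption_state())
  expect_equal(d$appearance_g_min, 0)
  expect_equal(d$d$mono, 0)
  expect_equal(d$d$intestine_mono, 0)
})

test_that("a pure monosaccharide bolus follows the two-compartment cascade closed form", {
  p <- absorption_params()
  kge <- p[["kge"]]; kabs <- p[["kabs"]]
  m0 <- 10
  s <- add_meal(absorption_state(), meal_event(0, mono_g = m0))
  r <- integrate_absorption(s, p, horizon = 600, dt = 0.02)
  closed <- kge * kabs * m0 * (exp(-kge * r$times) - exp(-kabs * r$times)) /
    (kabs - kge)
  expect_lt(max(abs(r$appearance - closed)), 1e-3)
  # cumulative appearance approaches the ingested mass
  expect_equal(r$state$cum_absorbed +
                 r$state$mono + r$state$intestine_mono, m0,
               tolerance = 1e-6)
})

test_that("lipids retard gastric emptying: appearance peak moves later", {
  p <- absorption_params()
  meal <- meal_event(0, mono_g = 10)
  plain <- integrate_absorption(add_meal(absorption_state(), meal), p, 600)
  fatty <- integrate_absorption(
    add_meal(absorption_state(), meal_event(0, mono_g = 10, lipid_g = 20)),
    p, 600)
  expect_gt(fatty$times[which.max(fatty$appearance)],
            plain$times[which.max(plain$appearance)])
})

test_that("higher glycemic index gives an earlier or equal starch appearance peak", {
  p <- absorption_params()
  peak_t <- vapply(c(0.5, 1.0, 1.5), function(gi) {
    r <- integrate_absorption(
      add_meal(absorption_state(), meal_event(0, starch_g = 30, gi = gi)),
      p, 900)
    r$times[which.max(r$appearance)]
  }, numeric(1))
  expect_true(all(diff(peak_t) <= 0))
})

test_that("appearance superposes across meals when no retardants are present", {
  p <- absorption_params()
  m1 <- meal_event(0, mono_g = 12)
  m2 <- meal_event(0, starch_g = 25, gi = 0.9)
  a1 <- integrate_absorption(add_meal(absorption_state(), m1), p, 400)
  a2 <- integrate_absorption(add_meal(absorption_state(), m2), p, 400)
  both <- integrate_absorption(add_meal(add_meal(absorption_state(), m1), m2),
                               p, 400)
  expect_equal(both$appearance, a1$appearance + a2$appearance,
               tolerance = 1e-10)
})

test_that("mass stays non-negative and conserved over a meal sequence", {
  p <- absorption_params()
  s <- add_meal(absorption_state(),
                meal_event(0, mono_g = 20, starch_g = 40, gi = 0.8,
                           lipid_g = 15, protein_g = 20, fiber_g = 6))
  dt <- 0.1
  total_in <- 60 + 15  # second meal adds 15 g digestible mid-digestion
  min_mass <- Inf
  for (k in 1:6000) {
    d <- absorption_deriv(s, p)
    s$mono <- s$mono + dt * d$d$mono
    s$lipid <- s$lipid + dt * d$d$lipid
    s$protein <- s$protein + dt * d$d$protein
    s$fiber <- s$fiber + dt * d$d$fiber
    s$starch$stomach_g <- s$starch$stomach_g + dt * d$d$starch$stomach_g
    s$starch$intestine_g <- s$starch$intestine_g + dt * d$d$starch$intestine_g
    s$intestine_mono <- s$intestine_mono + dt * d$d$intestine_mono
    s$cum_absorbed <- s$cum_absorbed + dt * d$d$cum_absorbed
    if (k == 2000)  # second meal lands mid-digestion
      s <- add_meal(s, meal_event(0, mono_g = 5, starch_g = 10, gi = 1.2))
    min_mass <- min(min_mass, s$mono, s$lipid, s$protein, s$fiber,
                    s$starch$stomach_g, s$starch$intestine_g,
                    s$intestine_mono)
  }
  expect_gte(min_mass, -1e-9)
  digestible <- s$mono + sum(s$starch$stomach_g) + sum(s$starch$intestine_g) +
    s$intestine_mono + s$cum_absorbed
  expect_equal(digestible, total_in, tolerance = 1e-6)
})

test_that("glucose input rate converts g/min to mmol/l/min in the distribution volume", {
  expect_equal(glucose_input_rate(0, body_weight_kg = 80), 0)
  expect_equal(glucose_input_rate(0.18016, vg = 0.187, body_weight_kg = 80),
               1 / (0.187 * 80), tolerance = 1e-12)
  expect_equal(glucose_input_rate(0.5, body_weight_kg = 160),
               glucose_input_rate(0.5, body_weight_kg = 80) / 2)
  expect_error(glucose_input_rate(0.1, vg = -1, body_weight_kg = 80))
  expect_error(glucose_input_rate(-0.1, body_weight_kg = 80))
})
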