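test_that("the pancreatic release fraction has the stated shape", {
  expect_identical(endogenous_release_fraction(9, 9, 3.205), 0.5)
  expect_identical(endogenous_release_fraction(0), 0)
  # scalar evaluation at twice the half-maximal glycaemia
  r <- 2^3.205
  expect_equal(endogenous_release_fraction(18, 9, 3.205), r / (1 + r),
               tolerance = 1e-12)
  g <- seq(0.1, 60, by = 0.1)
  f <- endogenous_release_fraction(g)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
  expect_gt(endogenous_release_fraction(500), 0.999)
})

test_that("injection fills a fresh depot with dose * 6000 / kgBW", {
  st <- model_state(g = 9, i = 50)
  st2 <- inject_insulin(st, insulin_event(0, 10, "rapid"), 80)
  expect_equal(st2$depots$s1, 750)
  expect_equal(st2$depots$s2, 0)
  expect_equal(st2$i, 50)

  # total depot mass grows by exactly the injected amount
  st3 <- inject_insulin(st2, insulin_event(0, 4, "long"), 80)
  expect_equal(sum(st3$depots$s1) - sum(st2$depots$s1), 4 * 6000 / 80)
  # per-administration depots keep distinct absorption times
  expect_equal(st3$depots$t_max_I, c(55, 600))

  expect_error(inject_insulin(st, data.frame(time = 0, dose_iu = -1,
                                             t_max_I = 55), 80), "> 0")
})

test_that("decoupled derivatives reduce to pure insulin decay", {
  p <- glycemia_params(kxgi = 1e-300, tgh = 1e-300, tigmax = 1e-300)
  st <- model_state(g = 7, i = 40)
  d <- glycemia_deriv(st, p, delta_a_monosac = 0, g_delayed = 7)
  expect_equal(d$dg, 0, tolerance = 1e-12)
  expect_equal(d$di, -p[["kxi"]] * 40, tolerance = 1e-12)
})

test_that("the basal steady state zeroes both balances (independent 2-D solve)", {
  p <- glycemia_params()
  # independent oracle: minimize the squared residuals of the algebraic system
  obj <- function(x) {
    st <- model_state(g = x[1], i = x[2])
    d <- glycemia_deriv(st, p, 0, g_delayed = x[1])
    d$dg^2 + d$di^2
  }
  opt <- optim(c(9, 30), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 5000))
  ss <- steady_state(p)
  expect_equal(unname(ss["G"]), opt$par[1], tolerance = 1e-4)
  expect_equal(unname(ss["I"]), opt$par[2], tolerance = 1e-4)
  d <- glycemia_deriv(model_state(g = ss[["G"]], i = ss[["I"]]), p, 0,
                      g_delayed = ss[["G"]])
  expect_equal(d$dg, 0, tolerance = 1e-10)
  expect_equal(d$di, 0, tolerance = 1e-10)
})

test_that("a single depot delivers its whole content to plasma (linear chain)", {
  # with negligible insulin elimination and endogenous release,
  # I(inf) - I(0) = S1(0) / V_I
  p <- glycemia_params(kxi = 1e-12, tigmax = 1e-12, tgh = 1e-6)
  log <- patient_log(body_weight_kg = 80,
                     insulins = insulin_event(0, 6, t_max_I = 55,
                                              product = "custom"),
                     duration = 4000)
  tr <- simulate_glucose(log, p, out_times = c(0, 4000), restart = FALSE,
                         g0 = 9, i0 = 0)
  s1_0 <- 6 * 6000 / 80
  expect_equal(tr$I[2] - tr$I[1], s1_0 / p[["vi"]], tolerance = 1e-6)
})

test_that("a zero-event run started at the steady state stays there for 24 h", {
  p <- glycemia_params()
  ss <- steady_state(p)
  log <- patient_log(body_weight_kg = 80, duration = 1440)
  tr <- simulate_glucose(log, p, out_times = seq(0, 1440, 5),
                         g0 = ss[["G"]], i0 = ss[["I"]])
  expect_lt(max(abs(tr$G - ss[["G"]])), 1e-6)
  expect_lt(max(abs(tr$I - ss[["I"]])), 1e-6)
})

test_that("halving the integration step leaves the trajectory unchanged to 1e-6", {
  log <- six_hour_scenario()
  t1 <- simulate_glucose(log, out_times = seq(0, 360, 5), g0 = 9, step = 1)
  t2 <- simulate_glucose(log, out_times = seq(0, 360, 5), g0 = 9, step = 0.5)
  expect_lt(max(abs(t1$G - t2$G)), 1e-6)
})

test_that("RK4 matches a small-step explicit-Euler oracle on a meal + bolus scenario", {
  log <- six_hour_scenario()
  p <- glycemia_params()
  i0 <- steady_state(p)[["I"]]
  rk4 <- simulate_glucose(log, p, out_times = seq(0, 360, 5), g0 = 9,
                          i0 = i0, step = 1)
  eul <- euler_oracle(log, p, g0 = 9, i0 = i0, horizon = 360, dt = 0.01)
  expect_lt(max(abs(rk4$G - eul$G)), 1e-3)
})

test_that("insulin mass balance: dose = depot residual + cumulative appearance", {
  vp <- nf_patient(days = 3)
  tr <- simulate_glucose(vp$log, vp$params, restart = FALSE)
  b <- attr(tr, "balance")
  expect_equal(b$insulin_injected_pmol_kg,
               b$insulin_depot_pmol_kg + b$insulin_appeared_pmol_kg,
               tolerance = 1e-6)
})

test_that("carbohydrate mass balance holds over a 3-day log", {
  vp <- nf_patient(days = 3)
  tr <- simulate_glucose(vp$log, vp$params, restart = FALSE)
  b <- attr(tr, "balance")
  expect_equal(b$ingested_g, b$stomach_g + b$intestine_g + b$absorbed_g,
               tolerance = 1e-6)
})

test_that("G and I remain non-negative across admissible parameter draws", {
  vp <- nf_patient(days = 2, seed = 17)
  set.seed(99)
  space <- parameter_space(3)
  for (k in 1:8) {
    m <- runif(3, 0.2, 5)
    tr <- simulate_glucose(vp$log, apply_multipliers(space, m),
                           restart = FALSE, on_blowup = "na")
    expect_true(all(tr$G > 0, na.rm = TRUE))
    expect_true(all(tr$I >= 0, na.rm = TRUE))
  }
})

test_that("restart resets glucose only, and reduces the error of a biased start", {
  st <- model_state(t = 10, g = 9, i = 50,
                    depots = data.frame(s1 = 100, s2 = 20, t_max_I = 55))
  meas <- data.frame(time = 10, value = 6.5, source = "fingerstick")
  st2 <- restart_state(st, meas)
  expect_equal(st2$g, 6.5)
  expect_equal(st2$i, 50)
  expect_equal(st2$depots, st$depots)
  # fixed point: restarting at the current value changes nothing
  st3 <- restart_state(st, data.frame(time = 10, value = 9,
                                      source = "fingerstick"))
  expect_equal(st3$g, st$g)
  expect_error(restart_state(st, data.frame(time = 10, value = 5,
                                            source = "cgms")), "fingerstick")

  # a +2 mmol/l initial-condition error: restarts cut the full-run RMSE
  vp <- nf_patient(days = 2, seed = 17)
  truth <- vp$truth
  g0_bad <- truth$G[1] + 2
  with_rs <- simulate_glucose(vp$log, vp$params, out_times = truth$t,
                              g0 = g0_bad, restart = TRUE)
  without_rs <- simulate_glucose(vp$log, vp$params, out_times = truth$t,
                                 g0 = g0_bad, restart = FALSE)
  rmse <- function(x) sqrt(mean((x$G - truth$G)^2))
  expect_lt(rmse(with_rs), rmse(without_rs))
})

test_that("a constant all-ones profile reproduces the unprofiled model bit for bit", {
  vp <- nf_patient(days = 2, seed = 17)
  prof <- diurnal_profile("kxi", rep(1, 4))
  plain <- simulate_glucose(vp$log, vp$params, restart = FALSE)
  with_prof <- simulate_glucose(vp$log, vp$params, profile = prof,
                                restart = FALSE)
  expect_identical(plain$G, with_prof$G)
  expect_identical(plain$I, with_prof$I)
})

test_that("trajectory blow-up is reported with the parameter vector", {
  vp <- nf_patient(days = 2, seed = 17)
  bad <- glycemia_params(kxgi = 3.11e-5 * 1e6)
  expect_error(simulate_glucose(vp$log, bad, restart = FALSE),
               "blow-up.*kxgi", ignore.case = TRUE)
})
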