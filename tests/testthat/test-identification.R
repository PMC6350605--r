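test_that("prediction fitness is zero for a perfect model and scales with offset", {
  p <- glycemia_params()
  ss <- steady_state(p)
  log0 <- self_consistent_log(p)
  expect_equal(fitness(log0, p, g0 = ss[["G"]], i0 = ss[["I"]]), 0,
               tolerance = 1e-10)
  log2 <- self_consistent_log(p, offset = 2)
  expect_equal(fitness(log2, p, g0 = ss[["G"]], i0 = ss[["I"]]), 2,
               tolerance = 1e-10)
  expect_error(fitness(patient_log(body_weight_kg = 70, duration = 10)),
               "CGMS")
})

test_that("unstable candidates get an infinite fitness, not a crash", {
  vp <- nf_patient(days = 2, seed = 17)
  expect_identical(fitness(vp$log, glycemia_params(kxgi = 3.11e-5 * 1e6)),
                   Inf)
})

test_that("OFAT sensitivity table has the right structure and baseline", {
  vp <- nf_patient(days = 2, seed = 17)
  space <- parameter_space(3)
  mult <- c(0.6, 1, 1.6)
  tab <- ofat_sensitivity(vp$log, space, mult)
  expect_equal(nrow(tab), length(space$names) * length(mult))
  base_rows <- tab[abs(tab$multiplier - 1) < 1e-12, ]
  expect_equal(length(unique(base_rows$fitness)), 1)
  # the dominant-uptake parameter must move the fitness
  kx <- tab[tab$parameter == "kxgi", ]
  expect_gt(max(kx$fitness) - min(kx$fitness), 0)
  expect_error(ofat_sensitivity(vp$log, space, c(0.5, 1.5)), "1.0")
})

test_that("brute force walks the documented additive grid", {
  vp <- nf_patient(days = 1, seed = 23)
  cfg <- training_config("brute_force")
  # default grid: 7 steps of 20% centred at 1
  k <- (cfg$steps - 1) / 2
  expect_equal(1 + (-k:k) * cfg$step_size,
               c(0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6))
  # degenerate one-point grid returns the reference values
  res1 <- brute_force(vp$log, parameter_space(3),
                      training_config("brute_force", steps = 1))
  expect_equal(unname(res1$multipliers), c(1, 1, 1))
  expect_equal(res1$n_eval, 1)
})

test_that("the GA honours elitism, bounds and seeded determinism", {
  vp <- nf_patient(days = 1, seed = 23)
  space <- parameter_space(3)
  cfg <- training_config("ga_fast", seed = 7, pop_size = 6, generations = 4)
  ref_fit <- fitness(vp$log, glycemia_params())
  r1 <- ga_optimize(vp$log, space, cfg)
  # reference vector seeded into the population + best-ever tracking
  expect_lte(r1$fitness, ref_fit)
  expect_true(all(r1$multipliers >= space$lower &
                    r1$multipliers <= space$upper))
  r2 <- ga_optimize(vp$log, space, cfg)
  expect_identical(r1$multipliers, r2$multipliers)
  expect_identical(r1$fitness, r2$fitness)
  expect_equal(r1$n_eval, 6 * (4 + 1))
})

test_that("Nelder-Mead converges on an analytic surrogate and improves monotonically", {
  space <- parameter_space(3)
  # surrogate with a known optimum at (1.1, 1.1, 1.1)
  surrogate <- function(m) sum((m - 1.1)^2)
  res <- nelder_mead_refine(space = space, start = c(1, 1, 1),
                            objective = surrogate)
  expect_equal(unname(res$multipliers), rep(1.1, 3), tolerance = 1e-4)

  # stationarity: starting at the optimum stays there
  res0 <- nelder_mead_refine(space = space, start = rep(1.1, 3),
                             objective = surrogate)
  expect_equal(unname(res0$multipliers), rep(1.1, 3), tolerance = 1e-6)

  # refinement never worsens a GA result on real fitness
  vp <- nf_patient(days = 1, seed = 23)
  ga <- ga_optimize(vp$log, space,
                    training_config("ga_fast", seed = 3, pop_size = 6,
                                    generations = 3))
  nm <- nelder_mead_refine(vp$log, space, ga)
  expect_lte(nm$fitness, ga$fitness)
  expect_true(all(nm$multipliers >= space$lower &
                    nm$multipliers <= space$upper))
})

test_that("identifiable parameter combinations are recovered from planted data", {
  # the model is invariant under joint scaling of (kxgi, vi); the
  # identifiable quantities in the 3-parameter space are kxgi/vi and kxi
  vp <- nf_patient(c(kxgi = 0.8, kxi = 1.2, vi = 1.0), days = 3, seed = 11)
  ga <- ga_optimize(vp$log, parameter_space(3),
                    training_config("ga_fast", seed = 5))
  nm <- nelder_mead_refine(vp$log, parameter_space(3), ga)
  m <- nm$multipliers
  expect_equal(unname(m["kxgi"] / m["vi"]), 0.8, tolerance = 0.02)
  expect_equal(unname(m["kxi"]), 1.2, tolerance = 0.02)
})

test_that("training config presets match their published settings", {
  slow <- training_config("ga_slow")
  expect_equal(slow[c("pop_size", "generations", "p_crossover", "p_mutation")],
               list(pop_size = 50, generations = 50, p_crossover = 0.9,
                    p_mutation = 0.2))
  fast <- training_config("ga_fast")
  expect_equal(fast[c("pop_size", "generations", "p_crossover", "p_mutation")],
               list(pop_size = 10, generations = 10, p_crossover = 0.9,
                    p_mutation = 0.01))
  expect_error(training_config("ga_fast", nonsense = 1), "unknown")
  expect_error(parameter_space(3, lower = 1.5), "contain 1.0")
  expect_error(brute_force(config = training_config("brute_force", steps = 4)),
               "odd")
})
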