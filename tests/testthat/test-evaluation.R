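test_that("error metrics follow their definitions", {
  ref <- c(5, 6, 7)
  m0 <- error_metrics(ref, ref)
  expect_equal(m0[c("average", "max", "variance", "rmse")],
               list(average = 0, max = 0, variance = 0, rmse = 0))

  m2 <- error_metrics(ref + 2, ref)
  expect_equal(m2[c("average", "max", "variance", "rmse")],
               list(average = 2, max = 2, variance = 0, rmse = 2))

  m <- error_metrics(c(1, -2, 3) + ref, ref)
  expect_equal(m$average, 2)
  expect_equal(m$max, 3)
  expect_equal(m$rmse, sqrt(14 / 3))

  expect_error(error_metrics(numeric(0), numeric(0)), "pairs")
})

test_that("RMSE dominates the mean absolute error on random series", {
  set.seed(4)
  for (k in 1:20) {
    e <- rnorm(50, sd = runif(1, 0.1, 3))
    m <- error_metrics(e, numeric(50))
    expect_gte(m$rmse, m$average)
  }
})

test_that("Clarke zones match the published grid on the worked cases", {
  expect_equal(as.character(ega_classify(6.5, 6.5)), "A")
  # overprediction in the hypoglycaemic range is dangerous
  expect_equal(as.character(ega_classify(7, 3)), "D")
  # moderate underestimation of high glucose is clinically acceptable
  expect_equal(as.character(ega_classify(8, 12)), "B")
  # opposite-extreme errors are the worst zone
  expect_equal(as.character(ega_classify(12, 3)), "E")
  expect_equal(as.character(ega_classify(3, 12)), "E")
  # large overprediction of a normal value confuses treatment
  expect_equal(as.character(ega_classify(12, 5.5)), "C")

  # unit invariance: classifying in mg/dl gives the same zones
  set.seed(8)
  p <- runif(200, 2, 20); r <- runif(200, 2, 20)
  expect_identical(ega_classify(p, r),
                   ega_classify(p * 18.016, r * 18.016, unit = "mg_dl"))
})

test_that("every pair lands in exactly one zone and fractions sum to 1", {
  set.seed(9)
  p <- runif(500, 1, 25); r <- runif(500, 1, 25)
  rep_ <- ega_report(p, r)
  expect_equal(sum(rep_$fractions), 1)
  expect_equal(length(rep_$zones), 500)
  expect_false(anyNA(rep_$zones))
  expect_equal(rep_$acceptable,
               unname(rep_$fractions["A"] + rep_$fractions["B"]))
})

test_that("full runs pair predictions with the CGMS and honour the restart flag", {
  vp <- nf_patient(days = 2, seed = 17)
  pp <- glycemia_params(kxgi = 3.11e-5 * 1.3, kxi = 1.211e-2 * 0.8)
  on <- full_run(vp$log, pp, restart = TRUE)
  off <- full_run(vp$log, pp, restart = FALSE)
  expect_equal(nrow(on), sum(vp$log$measurements$source == "cgms"))
  expect_equal(on$time, off$time)
  expect_lte(error_metrics(on)$rmse, error_metrics(off)$rmse)

  # no fingersticks: restart on and off coincide
  log_nofs <- patient_log(
    vp$log$patient_id, vp$log$body_weight_kg, vp$log$meals, vp$log$insulins,
    vp$log$measurements[vp$log$measurements$source == "cgms", ],
    duration = vp$log$duration)
  expect_identical(full_run(log_nofs, pp, restart = TRUE)$predicted,
                   full_run(log_nofs, pp, restart = FALSE)$predicted)
})

test_that("meal-wise errors grow with the prediction horizon", {
  vp <- nf_patient(days = 2, seed = 17)
  pp <- glycemia_params(kxgi = 3.11e-5 * 1.3, kxi = 1.211e-2 * 0.8)
  mw <- meal_wise_test(vp$log, pp)
  rmse <- vapply(mw$results, function(r) r$metrics$rmse, numeric(1))
  expect_true(all(diff(rmse) >= 0))
  expect_equal(length(mw$meals_used), length(unique(vp$log$meals$time)))

  # single-meal pooling equals the single meal's own metrics
  one <- meal_wise_test(vp$log, pp, horizons = 60,
                        meal_times = vp$log$meals$time[1])
  sel <- mw$pairs[mw$pairs$meal == vp$log$meals$time[1] & mw$pairs$dt <= 60, ]
  expect_equal(one$results[[1]]$metrics$rmse,
               sqrt(mean((sel$predicted - sel$reference)^2)))

  # meals without a CGMS anchor are skipped with a warning
  sparse <- vp$log
  keep <- sparse$measurements$time > 600
  sparse <- patient_log(sparse$patient_id, sparse$body_weight_kg,
                        sparse$meals, sparse$insulins,
                        sparse$measurements[keep, ],
                        duration = sparse$duration)
  expect_warning(meal_wise_test(sparse, pp, horizons = 60), "no CGMS anchor")
})

test_that("sliding-window cross-validation averages per-fold meal-wise RMSE", {
  vp <- nf_patient(days = 3, seed = 11)
  cv <- cross_validate(vp$log, train_days = 1, positions = 2, seed = 50,
                       method = "brute_force", refine = FALSE,
                       steps = 3)
  expect_equal(cv$mean_rmse, mean(cv$folds$rmse))
  expect_equal(nrow(cv$folds), 2)
  # a single position is a plain train/test split
  cv1 <- cross_validate(vp$log, train_days = 1, positions = 1, seed = 50,
                        method = "brute_force", refine = FALSE, steps = 3)
  expect_equal(cv1$mean_rmse, cv1$folds$rmse[1])
  expect_error(cross_validate(vp$log, train_days = 2, positions = 12),
               "at most")
})

test_that("the improvement t-test is a Welch test with sane degenerate cases", {
  same <- improvement_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  a <- c(1, 2, 3, 4, 5); b <- c(3, 4, 5, 6, 7)
  res <- improvement_ttest(a, b)
  # Welch statistic recomputed from first principles
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_hand <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(t_hand, df), tolerance = 1e-12)
  expect_false(res$significant)

  sw <- improvement_ttest(b, a)
  expect_equal(sw$t, -res$t)
  expect_equal(sw$p, res$p)

  const <- improvement_ttest(c(2, 2), c(2, 2))
  expect_equal(const[c("t", "p")], list(t = 0, p = 1))
})
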