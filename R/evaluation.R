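#' Error summaries of a prediction
#'
#' Standard figures of merit on `predicted - reference`: mean absolute
#' error, maximal absolute error, variance of the signed error and RMSE
#' (all mmol/l).
#'
#' @param result a `"prediction_result"` from [full_run()], or a numeric
#'   vector of predictions.
#' @param reference reference values (when `result` is a plain vector).
#' @return Named list `average`, `max`, `variance`, `rmse`, `n`.
#' @export
error_metrics <- function(result, reference = NULL) {
  if (inherits(result, "prediction_result")) {
    e <- result$predicted - result$reference
  } else {
    if (is.null(reference)) stop("reference values required")
    e <- result - reference
  }
  e <- e[is.finite(e)]
  if (!length(e)) stop("no prediction pairs")
  list(average = mean(abs(e)), max = max(abs(e)),
       variance = if (length(e) > 1) var(e) else 0,
       rmse = sqrt(mean(e^2)), n = length(e))
}

#' Clarke Error Grid zone classification
#'
#' Classifies prediction--reference pairs into the clinical severity zones
#' A-E of Clarke Error Grid Analysis. Inputs in mmol/l are converted to
#' mg/dl (factor 18.016) and the published grid geometry is applied as
#' explicit region inequalities:
#' \itemize{
#'   \item A: prediction within 20% of reference, or both below 70 mg/dl;
#'   \item E: reference <= 70 and prediction >= 180, or reference >= 180 and
#'     prediction <= 70;
#'   \item C: (70 <= ref <= 290 and pred >= ref + 110) or
#'     (130 <= ref <= 180 and pred <= 7/5 ref - 182);
#'   \item D: (ref >= 240 and 70 <= pred <= 180) or
#'     (ref <= 175/3 and 70 <= pred <= 180) or
#'     (175/3 <= ref <= 70 and pred >= 6/5 ref);
#'   \item B: everything else.
#' }
#' Zone A is tested first, so points on a shared boundary fall in the less
#' severe zone.
#'
#' @param predicted,reference glucose values, mmol/l (vectorized, > 0).
#' @param unit `"mmol_l"` (default) or `"mg_dl"`.
#' @return Factor with levels A-E.
#' @examples
#' ega_classify(7, 3)    # overprediction in the hypoglycaemic range -> D
#' ega_classify(8, 12)   # clinically acceptable underestimation -> B
#' @export
ega_classify <- function(predicted, reference, unit = c("mmol_l", "mg_dl")) {
  unit <- match.arg(unit)
  if (any(predicted <= 0) || any(reference <= 0))
    stop("glucose values must be positive")
  k <- if (unit == "mmol_l") 18.016 else 1
  p <- predicted * k
  r <- reference * k
  zone <- rep("B", length(p))
  a <- abs(p - r) <= 0.2 * r | (r < 70 & p < 70)
  e <- (r <= 70 & p >= 180) | (r >= 180 & p <= 70)
  cc <- (r >= 70 & r <= 290 & p >= r + 110) |
    (r >= 130 & r <= 180 & p <= (7 / 5) * r - 182)
  d <- (r >= 240 & p >= 70 & p <= 180) |
    (r <= 175 / 3 & p >= 70 & p <= 180) |
    (r >= 175 / 3 & r <= 70 & p >= (6 / 5) * r)
  zone[d] <- "D"; zone[cc] <- "C"; zone[e] <- "E"; zone[a] <- "A"
  factor(zone, levels = c("A", "B", "C", "D", "E"))
}

#' @rdname ega_classify
#' @param result optionally, a `"prediction_result"` instead of two vectors.
#' @return `ega_report()` returns a list of class `"ega_report"` with per-pair
#'   `zones`, the zone `fractions` (summing to 1) and the clinically
#'   `acceptable` fraction A + B.
#' @export
ega_report <- function(predicted, reference, result = NULL) {
  if (!is.null(result)) {
    predicted <- result$predicted; reference <- result$reference
  }
  z <- ega_classify(predicted, reference)
  fr <- as.numeric(table(z)) / length(z)
  names(fr) <- levels(z)
  structure(list(zones = z, fractions = fr,
                 acceptable = unname(fr["A"] + fr["B"]), n = length(z)),
            class = "ega_report")
}

#' @export
print.ega_report <- function(x, ...) {
  cat("Clarke Error Grid Analysis (", x$n, " pairs):\n", sep = "")
  print(round(x$fractions, 4))
  cat(sprintf("Clinically acceptable (A+B): %.1f%%\n", 100 * x$acceptable))
  invisible(x)
}

new_prediction_result <- function(time, predicted, reference, protocol) {
  structure(data.frame(time = time, predicted = predicted,
                       reference = reference),
            class = c("prediction_result", "data.frame"),
            protocol = protocol)
}

#' Continuous full-log prediction run
#'
#' Simulates the whole log with all meals and injections applied and pairs
#' the model glucose with every CGMS reading. With `restart = TRUE` the model
#' is reset to each fingerstick value (the realistic deployment protocol);
#' predictions are recorded before the reset at coincident timestamps.
#'
#' @inheritParams simulate_glucose
#' @return A `"prediction_result"` data.frame `(time, predicted, reference)`.
#' @export
full_run <- function(log, params = glycemia_params(), profile = NULL,
                     restart = TRUE, absorption = absorption_params(),
                     step = 1) {
  cg <- log$measurements[log$measurements$source == "cgms", , drop = FALSE]
  if (!nrow(cg)) stop("full_run requires CGMS measurements")
  tr <- simulate_glucose(log, params, absorption, profile,
                         out_times = cg$time, step = step, restart = restart)
  new_prediction_result(cg$time, tr$G, cg$value,
                        list(protocol = "full_run", restart = restart))
}

#' Meal-wise prediction test
#'
#' Starts the model afresh at each meal -- glucose anchored to the nearest
#' CGMS reading within 10 minutes of the meal, insulin at its basal steady
#' state, stomach and depots empty, all earlier meals and injections ignored
#' -- and runs it over each horizon, applying only the events inside the
#' horizon. Errors are pooled across meals per horizon. The deliberately
#' discarded overlap of digestion and insulin evolution makes errors grow
#' with the horizon.
#'
#' @inheritParams full_run
#' @param horizons prediction horizons, min.
#' @param meal_times meal start times to use (default: every distinct meal
#'   time in the log). Meals without a CGMS anchor are skipped with a
#'   warning.
#' @param anchor_window maximal anchor distance, min.
#' @return A list of class `"meal_wise_result"`: per-horizon `metrics`,
#'   `ega` and pooled pairs, plus the anchors used.
#' @export
meal_wise_test <- function(log, params = glycemia_params(), profile = NULL,
                           horizons = c(60, 120, 240, 360),
                           meal_times = NULL,
                           absorption = absorption_params(), step = 1,
                           anchor_window = 10) {
  cg <- log$measurements[log$measurements$source == "cgms", , drop = FALSE]
  if (!nrow(cg)) stop("meal-wise test requires CGMS measurements")
  if (is.null(meal_times)) meal_times <- unique(log$meals$time)
  hmax <- max(horizons)
  pairs <- list()
  used <- numeric(0)
  for (t0 in sort(meal_times)) {
    di <- abs(cg$time - t0)
    if (min(di) > anchor_window) {
      warning("meal at t=", t0, " min has no CGMS anchor within ",
              anchor_window, " min; skipped")
      next
    }
    g0 <- cg$value[which.min(di)]
    t_end <- min(t0 + hmax, log$duration)
    sub <- function(df) {
      df <- df[df$time >= t0 & df$time <= t_end, , drop = FALSE]
      df$time <- df$time - t0
      df
    }
    cg_h <- cg[cg$time > t0 & cg$time <= t_end, , drop = FALSE]
    if (!nrow(cg_h)) next
    sublog <- patient_log(
      patient_id = log$patient_id, body_weight_kg = log$body_weight_kg,
      meals = sub(log$meals), insulins = sub(log$insulins),
      measurements = data.frame(time = cg_h$time - t0, value = cg_h$value,
                                source = "cgms", stringsAsFactors = FALSE),
      duration = t_end - t0,
      start_minute_of_day = log$start_minute_of_day + t0)
    tr <- simulate_glucose(sublog, params, absorption, profile,
                           out_times = cg_h$time - t0, step = step,
                           restart = FALSE, g0 = g0)
    pairs[[length(pairs) + 1]] <-
      data.frame(meal = t0, dt = cg_h$time - t0, predicted = tr$G,
                 reference = cg_h$value)
    used <- c(used, t0)
  }
  if (!length(pairs)) stop("no meal with a usable CGMS anchor")
  pairs <- do.call(rbind, pairs)
  per_h <- lapply(horizons, function(h) {
    sel <- pairs[pairs$dt <= h, , drop = FALSE]
    list(horizon = h,
         metrics = error_metrics(sel$predicted, sel$reference),
         ega = ega_report(sel$predicted, sel$reference))
  })
  names(per_h) <- paste0("h", horizons)
  structure(list(horizons = horizons, results = per_h, pairs = pairs,
                 meals_used = used),
            class = "meal_wise_result")
}

#' @export
print.meal_wise_result <- function(x, ...) {
  cat("Meal-wise prediction test (", length(x$meals_used), " meals):\n",
      sep = "")
  for (r in x$results)
    cat(sprintf("  %4d min: RMSE %.2f, avg %.2f, EGA A+B %.1f%% (n=%d)\n",
                r$horizon, r$metrics$rmse, r$metrics$average,
                100 * r$ega$acceptable, r$metrics$n))
  invisible(x)
}

#' Sliding-window cross-validation of the trained model
#'
#' Trains the personalized model on a sliding window (default 1 day wide,
#' advanced in 3-hour steps to 10 positions) and validates each trained model
#' by the pooled meal-wise RMSE at a short horizon on the meals outside the
#' training window; reports the average across positions.
#'
#' @inheritParams full_run
#' @param train_days training window width, days (1 or 2 in the reference
#'   protocol).
#' @param positions number of window positions.
#' @param slide_step window advance per position, min.
#' @param horizon validation prediction horizon, min.
#' @param seed base seed; position `i` trains with `seed + i`.
#' @param ... passed to [glucose_fit()] (e.g. `method`, `n_params`,
#'   `refine`, `diurnal`).
#' @return List with `mean_rmse`, per-fold data.frame `folds`, and the
#'   protocol settings.
#' @export
cross_validate <- function(log, train_days = 1, positions = 10,
                           slide_step = 180, horizon = 60, seed = NULL,
                           absorption = absorption_params(), step = 1, ...) {
  width <- train_days * 1440
  max_pos <- floor((log$duration - width) / slide_step) + 1
  if (positions > max_pos)
    stop("log too short for ", positions, " positions; at most ", max_pos,
         " feasible")
  rmse <- numeric(positions)
  for (i in seq_len(positions)) {
    start <- (i - 1) * slide_step
    train_log <- slice_window(log, start, width)
    fit <- glucose_fit(train_log,
                       seed = if (is.null(seed)) NULL else seed + i,
                       absorption = absorption, step = step, ...)
    out_meals <- setdiff(unique(log$meals$time),
                         unique(log$meals$time[log$meals$time >= start &
                                                 log$meals$time < start + width]))
    mw <- meal_wise_test(log, fit$params, fit$profile, horizons = horizon,
                         meal_times = out_meals, absorption = absorption,
                         step = step)
    rmse[i] <- mw$results[[1]]$metrics$rmse
  }
  list(mean_rmse = mean(rmse),
       folds = data.frame(position = seq_len(positions),
                          start = (seq_len(positions) - 1) * slide_step,
                          rmse = rmse),
       train_days = train_days, horizon = horizon)
}

#' Two-sample improvement test
#'
#' Welch two-sample t-test on two error series, used to judge whether a
#' protocol change improved the prediction errors at significance level
#' `alpha`.
#'
#' @param errors_a,errors_b numeric error series (length >= 2).
#' @param alpha significance level.
#' @return List `t`, `p`, `significant`.
#' @export
improvement_ttest <- function(errors_a, errors_b, alpha = 0.05) {
  stopifnot(length(errors_a) >= 2, length(errors_b) >= 2)
  if (var(errors_a) == 0 && var(errors_b) == 0) {
    if (mean(errors_a) == mean(errors_b))
      return(list(t = 0, p = 1, significant = FALSE))
    return(list(t = sign(mean(errors_a) - mean(errors_b)) * Inf, p = 0,
                significant = TRUE))
  }
  ht <- t.test(errors_a, errors_b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       significant = ht$p.value < alpha)
}
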