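#' Built-in subcutaneous insulin product registry
#'
#' Maps product identifiers to kind (bolus/basal) and time-to-maximum
#' absorption t_max,I in minutes. t_max,I is product dependent; these shipped
#' defaults cover the common classes (rapid analogs, regular human insulin,
#' intermediate NPH and long-acting analogs) and can be extended or overridden
#' when reading a log.
#'
#' @return data.frame with columns `product`, `kind`, `t_max_I`.
#' @export
insulin_products <- function() {
  data.frame(
    product = c("rapid", "regular", "nph", "long"),
    kind    = c("bolus", "bolus", "basal", "basal"),
    t_max_I = c(55, 90, 300, 600),
    stringsAsFactors = FALSE
  )
}

empty_meals <- function() {
  data.frame(time = numeric(0), mono_g = numeric(0), starch_g = numeric(0),
             gi = numeric(0), lipid_g = numeric(0), protein_g = numeric(0),
             fiber_g = numeric(0))
}

empty_insulins <- function() {
  data.frame(time = numeric(0), dose_iu = numeric(0),
             product = character(0), kind = character(0),
             t_max_I = numeric(0), stringsAsFactors = FALSE)
}

empty_measurements <- function() {
  data.frame(time = numeric(0), value = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a meal event row
#'
#' A meal is described by its decomposed nutrient content: free
#' monosaccharides, starch with a glycemic index, lipids, proteins and fibers.
#' A dish containing several starch sources with distinct glycemic indices is
#' represented as several meal rows at the same timestamp (the digestion model
#' is additive in meal mass).
#'
#' @param time minutes since log start (>= 0).
#' @param mono_g free monosaccharide mass, g.
#' @param starch_g starch mass, g.
#' @param gi glycemic index of the starch, in (0, 1.5].
#' @param lipid_g,protein_g,fiber_g masses, g.
#' @return one-row data.frame suitable for the `meals` slot of [patient_log()].
#' @export
meal_event <- function(time, mono_g = 0, starch_g = 0, gi = 1,
                       lipid_g = 0, protein_g = 0, fiber_g = 0) {
  stopifnot(time >= 0, mono_g >= 0, starch_g >= 0, lipid_g >= 0,
            protein_g >= 0, fiber_g >= 0, gi > 0, gi <= 1.5)
  data.frame(time = time, mono_g = mono_g, starch_g = starch_g, gi = gi,
             lipid_g = lipid_g, protein_g = protein_g, fiber_g = fiber_g)
}

#' Construct an insulin administration event row
#'
#' @param time minutes since log start.
#' @param dose_iu dose in insulin units (> 0).
#' @param product product identifier; resolved against [insulin_products()]
#'   unless `t_max_I` is given explicitly.
#' @param t_max_I time-to-maximum absorption, minutes; overrides the registry.
#' @param registry product registry data.frame (see [insulin_products()]).
#' @return one-row data.frame for the `insulins` slot of [patient_log()].
#' @export
insulin_event <- function(time, dose_iu, product = "rapid", t_max_I = NULL,
                          registry = insulin_products()) {
  stopifnot(time >= 0)
  if (!is.finite(dose_iu) || dose_iu <= 0) stop("insulin dose must be > 0")
  if (is.null(t_max_I)) {
    hit <- match(product, registry$product)
    if (is.na(hit))
      stop("unknown insulin product '", product,
           "'; supply t_max_I explicitly or extend the registry")
    t_max_I <- registry$t_max_I[hit]
    kind <- registry$kind[hit]
  } else {
    kind <- if (t_max_I >= 240) "basal" else "bolus"
  }
  if (t_max_I <= 0) stop("t_max_I must be > 0")
  data.frame(time = time, dose_iu = dose_iu, product = product, kind = kind,
             t_max_I = t_max_I, stringsAsFactors = FALSE)
}

#' Construct a patient lifestyle log
#'
#' The container for one patient's observation window: meals, subcutaneous
#' insulin administrations and glucose measurements (CGMS at ~5-minute
#' cadence plus sparse fingersticks), with the body weight needed by the
#' per-kgBW model parameters. Times are minutes since log start;
#' `start_minute_of_day` records the clock phase of t = 0 (needed by diurnal
#' profiles).
#'
#' @param patient_id character identifier.
#' @param body_weight_kg body weight, kg (> 0). Required.
#' @param meals data.frame of [meal_event()] rows.
#' @param insulins data.frame of [insulin_event()] rows.
#' @param measurements data.frame with columns `time`, `value` (mmol/l),
#'   `source` (`"cgms"` or `"fingerstick"`).
#' @param duration window length, minutes; defaults to the last event time.
#' @param start_minute_of_day clock minute-of-day of t = 0 (default 0,
#'   i.e. midnight).
#' @return An object of class `"patient_log"`.
#' @export
patient_log <- function(patient_id = "patient",
                        body_weight_kg,
                        meals = empty_meals(),
                        insulins = empty_insulins(),
                        measurements = empty_measurements(),
                        duration = NULL,
                        start_minute_of_day = 0) {
  if (missing(body_weight_kg) || is.null(body_weight_kg) ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body_weight_kg is required and must be a positive number")
  meals <- as.data.frame(meals)
  insulins <- as.data.frame(insulins)
  measurements <- as.data.frame(measurements)

  for (nm in c("meals", "insulins", "measurements")) {
    df <- get(nm)
    if (nrow(df) && is.unsorted(df$time)) {
      warning("unsorted ", nm, " rows; sorting by time")
      assign(nm, df[order(df$time), , drop = FALSE])
    }
  }
  row.names(meals) <- row.names(insulins) <- row.names(measurements) <- NULL

  if (nrow(measurements)) {
    if (any(measurements$value <= 0)) stop("glucose values must be > 0")
    if (!all(measurements$source %in% c("cgms", "fingerstick")))
      stop("measurement source must be 'cgms' or 'fingerstick'")
    cg <- measurements$time[measurements$source == "cgms"]
    if (length(cg) > 1 && any(diff(cg) <= 0))
      stop("CGMS series must be strictly increasing in time")
  }
  if (is.null(duration)) {
    duration <- max(0, meals$time, insulins$time, measurements$time)
  }
  all_t <- c(meals$time, insulins$time, measurements$time)
  if (length(all_t) && (any(all_t < 0) || any(all_t > duration)))
    stop("all event times must lie within [0, duration]")

  structure(
    list(patient_id = patient_id, body_weight_kg = body_weight_kg,
         meals = meals, insulins = insulins, measurements = measurements,
         duration = duration,
         start_minute_of_day = start_minute_of_day %% 1440),
    class = "patient_log")
}

#' @export
print.patient_log <- function(x, ...) {
  n_cg <- sum(x$measurements$source == "cgms")
  n_fs <- sum(x$measurements$source == "fingerstick")
  cat(sprintf(
    "Patient log '%s': %.1f days, %d meal rows, %d insulin doses,\n  %d CGMS samples, %d fingersticks, body weight %.1f kg\n",
    x$patient_id, x$duration / 1440, nrow(x$meals), nrow(x$insulins),
    n_cg, n_fs, x$body_weight_kg))
  invisible(x)
}

#' Slice a time window out of a patient log
#'
#' Keeps exactly the events and measurements with `start <= time < start +
#' width` (half-open interval, so adjacent windows partition the log) and
#' re-bases times to 0. The clock phase is advanced accordingly.
#'
#' @param log a [patient_log()].
#' @param start window start, minutes (>= 0).
#' @param width window width, minutes; `start + width` must not exceed the
#'   log duration.
#' @return A [patient_log()] of duration `width`.
#' @export
slice_window <- function(log, start, width) {
  stopifnot(inherits(log, "patient_log"), start >= 0, width >= 0,
            start + width <= log$duration)
  cut <- function(df) {
    df <- df[df$time >= start & df$time < start + width, , drop = FALSE]
    df$time <- df$time - start
    row.names(df) <- NULL
    df
  }
  patient_log(patient_id = log$patient_id,
              body_weight_kg = log$body_weight_kg,
              meals = cut(log$meals), insulins = cut(log$insulins),
              measurements = cut(log$measurements), duration = width,
              start_minute_of_day = log$start_minute_of_day + start)
}
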