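#' Read and write patient lifestyle logs
#'
#' Logs are stored either as a flat CSV with one row per event and a `type`
#' discriminator column, or as a JSON mirror of the [patient_log()] structure.
#'
#' CSV columns: `time` (min), `type` (one of `log`, `weight`, `meal`,
#' `insulin`, `cgms`, `fingerstick`), `patient_id` and `start_minute_of_day`
#' (on the `log` row), `value` + `unit` (glucose rows: `mmol_l` or `mg_dl`,
#' converted with 18.016 (mg/dl)/(mmol/l); weight rows: `kg`), nutrient
#' columns `mono_g, starch_g, gi, lipid_g, protein_g, fiber_g` (meal rows),
#' and `dose_iu, product, kind, t_max_I` (insulin rows). A missing `t_max_I`
#' is resolved from the product registry.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"csv"`, `"json"` or `"auto"`.
#' @param registry insulin product registry, see [insulin_products()].
#' @param default_t_max_I fallback time-to-maximum absorption (min) for
#'   products absent from the registry; without it an unknown product is an
#'   error.
#' @return [read_patient_log()] returns a [patient_log()];
#'   [write_patient_log()] returns `path` invisibly.
#' @export
read_patient_log <- function(path, format = c("auto", "csv", "json"),
                             registry = insulin_products(),
                             default_t_max_I = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    as_df <- function(d, empty) {
      if (is.null(d) || (is.data.frame(d) && !nrow(d)) || !length(d)) empty
      else as.data.frame(d)
    }
    return(patient_log(
      patient_id = x$patient_id, body_weight_kg = x$body_weight_kg,
      meals = as_df(x$meals, empty_meals()),
      insulins = as_df(x$insulins, empty_insulins()),
      measurements = as_df(x$measurements, empty_measurements()),
      duration = x$duration,
      start_minute_of_day = x$start_minute_of_day))
  }

  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("time", "type"), names(d))
  if (length(need)) stop("log CSV misses columns: ", paste(need, collapse = ", "))
  col <- function(nm, default = NA) if (nm %in% names(d)) d[[nm]] else
    rep(default, nrow(d))

  wrow <- which(d$type == "weight")
  if (!length(wrow)) stop("log has no body-weight record")
  weight <- as.numeric(col("value")[wrow[1]])

  lrow <- which(d$type == "log")
  pid <- if (length(lrow)) as.character(col("patient_id", "patient")[lrow[1]]) else "patient"
  if (is.na(pid) || !nzchar(pid)) pid <- "patient"
  smod <- if (length(lrow)) as.numeric(col("start_minute_of_day", 0)[lrow[1]]) else 0
  if (is.na(smod)) smod <- 0
  duration <- if (length(lrow)) as.numeric(col("value")[lrow[1]]) else NULL
  if (length(duration) && is.na(duration)) duration <- NULL

  m <- d[d$type == "meal", , drop = FALSE]
  meals <- if (nrow(m)) data.frame(
    time = as.numeric(m$time),
    mono_g = as.numeric(col("mono_g", 0)[d$type == "meal"]),
    starch_g = as.numeric(col("starch_g", 0)[d$type == "meal"]),
    gi = as.numeric(col("gi", 1)[d$type == "meal"]),
    lipid_g = as.numeric(col("lipid_g", 0)[d$type == "meal"]),
    protein_g = as.numeric(col("protein_g", 0)[d$type == "meal"]),
    fiber_g = as.numeric(col("fiber_g", 0)[d$type == "meal"])
  ) else empty_meals()
  nafix <- function(x) { x[is.na(x)] <- 0; x }
  if (nrow(meals)) {
    meals[c("mono_g", "starch_g", "lipid_g", "protein_g", "fiber_g")] <-
      lapply(meals[c("mono_g", "starch_g", "lipid_g", "protein_g", "fiber_g")], nafix)
    meals$gi[is.na(meals$gi)] <- 1
  }

  ii <- d$type == "insulin"
  insulins <- if (any(ii)) {
    tm <- as.numeric(col("t_max_I")[ii])
    prod <- as.character(col("product", "rapid")[ii])
    kind <- as.character(col("kind")[ii])
    rows <- lapply(seq_len(sum(ii)), function(k) {
      if (is.na(tm[k])) {
        hit <- match(prod[k], registry$product)
        if (is.na(hit)) {
          if (is.null(default_t_max_I))
            stop("unknown insulin product '", prod[k],
                 "' and no default_t_max_I supplied")
          tm[k] <- default_t_max_I
        } else tm[k] <- registry$t_max_I[hit]
      }
      insulin_event(as.numeric(d$time[ii][k]),
                    as.numeric(col("dose_iu")[ii][k]),
                    product = prod[k], t_max_I = tm[k], registry = registry)
    })
    kk <- do.call(rbind, rows)
    kk$kind <- ifelse(is.na(kind) | !nzchar(kind), kk$kind, kind)
    kk
  } else empty_insulins()

  gi_rows <- d$type %in% c("cgms", "fingerstick")
  measurements <- if (any(gi_rows)) {
    v <- as.numeric(col("value")[gi_rows])
    u <- as.character(col("unit", "mmol_l")[gi_rows])
    u[is.na(u) | !nzchar(u)] <- "mmol_l"
    bad <- !u %in% c("mmol_l", "mg_dl")
    if (any(bad)) stop("unknown glucose unit: ", paste(unique(u[bad]), collapse = ", "))
    v[u == "mg_dl"] <- v[u == "mg_dl"] / 18.016
    data.frame(time = as.numeric(d$time[gi_rows]), value = v,
               source = d$type[gi_rows], stringsAsFactors = FALSE)
  } else empty_measurements()

  patient_log(patient_id = pid, body_weight_kg = weight, meals = meals,
              insulins = insulins, measurements = measurements,
              duration = duration, start_minute_of_day = smod)
}

#' @param log a [patient_log()] to serialize.
#' @rdname read_patient_log
#' @export
write_patient_log <- function(log, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(log, "patient_log"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(
      list(patient_id = log$patient_id,
           body_weight_kg = log$body_weight_kg,
           duration = log$duration,
           start_minute_of_day = log$start_minute_of_day,
           meals = log$meals, insulins = log$insulins,
           measurements = log$measurements),
      path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    return(invisible(path))
  }
  blank <- function(n) rep(NA, n)
  row0 <- data.frame(
    time = 0, type = "log", patient_id = log$patient_id,
    start_minute_of_day = log$start_minute_of_day,
    value = log$duration, unit = "min",
    mono_g = NA, starch_g = NA, gi = NA, lipid_g = NA, protein_g = NA,
    fiber_g = NA, dose_iu = NA, product = NA, kind = NA, t_max_I = NA,
    stringsAsFactors = FALSE)
  roww <- row0; roww$type <- "weight"; roww$value <- log$body_weight_kg
  roww$unit <- "kg"; roww$patient_id <- NA; roww$start_minute_of_day <- NA
  mk <- function(n, time, type) data.frame(
    time = time, type = type, patient_id = blank(n),
    start_minute_of_day = blank(n), value = blank(n), unit = blank(n),
    mono_g = blank(n), starch_g = blank(n), gi = blank(n),
    lipid_g = blank(n), protein_g = blank(n), fiber_g = blank(n),
    dose_iu = blank(n), product = blank(n), kind = blank(n),
    t_max_I = blank(n), stringsAsFactors = FALSE)
  out <- list(row0, roww)
  if (nrow(log$meals)) {
    r <- mk(nrow(log$meals), log$meals$time, "meal")
    r[c("mono_g", "starch_g", "gi", "lipid_g", "protein_g", "fiber_g")] <-
      log$meals[c("mono_g", "starch_g", "gi", "lipid_g", "protein_g", "fiber_g")]
    out <- c(out, list(r))
  }
  if (nrow(log$insulins)) {
    r <- mk(nrow(log$insulins), log$insulins$time, "insulin")
    r[c("dose_iu", "product", "kind", "t_max_I")] <-
      log$insulins[c("dose_iu", "product", "kind", "t_max_I")]
    out <- c(out, list(r))
  }
  if (nrow(log$measurements)) {
    r <- mk(nrow(log$measurements), log$measurements$time,
            log$measurements$source)
    r$value <- log$measurements$value
    r$unit <- "mmol_l"
    out <- c(out, list(r))
  }
  write.csv(do.call(rbind, out), path, row.names = FALSE, na = "")
  invisible(path)
}
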