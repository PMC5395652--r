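#' Observation noise model
#'
#' Proportional-error model y_i = f_i (1 + sigma eps_i) with eps_i
#' standard normal or standard Student-t.  The heavy-tailed t family
#' with few degrees of freedom is the robust choice when outliers are
#' expected.
#'
#' @param family "gaussian" or "student_t"
#' @param sigma proportional scale (dimensionless, default 0.10)
#' @param df degrees of freedom for the t family (default 4)
#' @return object of class `noise_model`
#' @export
noise_model <- function(family = c("student_t", "gaussian"),
                        sigma = 0.10, df = 4) {
  family <- match.arg(family)
  if (sigma <= 0) stop("sigma must be positive")
  if (family == "student_t" && df <= 2)
    stop("df must exceed 2 for the default Student-t settings")
  structure(list(family = family, sigma = sigma,
                 df = if (family == "student_t") df else NA_real_),
            class = "noise_model")
}

#' Time-concentration dataset
#'
#' @param times observation times (minutes), strictly increasing
#' @param conc observed plasma concentrations (pM), > 0
#' @param timescale "short" (hours, dynamic model) or "long" (weeks,
#'   steady-state model applicable)
#' @param dose_mg administered dose (mg)
#' @param bodyweight_kg subject bodyweight (kg, default 90)
#' @param truth optional truth sidecar (e.g. the generating
#'   [test_input_params()]) so synthetic fixtures travel with their truth
#' @param meta optional named list of extra metadata (seed, noise, ...)
#' @return object of class `er_dataset`
#' @export
er_dataset <- function(times, conc, timescale = c("long", "short"),
                       dose_mg = NA_real_, bodyweight_kg = 90,
                       truth = NULL, meta = list()) {
  timescale <- match.arg(timescale)
  check_times(times)
  if (length(conc) != length(times)) stop("times/conc length mismatch")
  if (any(conc <= 0)) stop("concentrations must be positive")
  structure(list(times = as.numeric(times), conc = as.numeric(conc),
                 timescale = timescale, dose_mg = dose_mg,
                 bodyweight_kg = bodyweight_kg, truth = truth,
                 meta = meta),
            class = "er_dataset")
}

#' @export
print.er_dataset <- function(x, ...) {
  cat(sprintf("<er_dataset> %d observations, %s timescale, dose %s mg\n",
              length(x$times), x$timescale,
              format(x$dose_mg)))
  cat(sprintf("  t: %.3g..%.3g min, C: %.3g..%.3g pM\n",
              min(x$times), max(x$times), min(x$conc), max(x$conc)))
  invisible(x)
}

#' Write / read a dataset as CSV plus a JSON truth sidecar
#'
#' The CSV has columns `time_min` and `conc_pM`; dose, bodyweight,
#' timescale, noise settings, seed and (for synthetic data) the true
#' input parameters travel in `<path>.json`.
#'
#' @param dataset [er_dataset()]
#' @param path CSV file path
#' @return `read_dataset_csv` returns an `er_dataset`
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(data.frame(time_min = dataset$times, conc_pM = dataset$conc),
            path, row.names = FALSE, quote = FALSE)
  truth <- dataset$truth
  if (!is.null(truth)) truth <- unclass(truth)
  side <- list(timescale = dataset$timescale, dose_mg = dataset$dose_mg,
               bodyweight_kg = dataset$bodyweight_kg,
               truth = truth, meta = dataset$meta)
  jsonlite::write_json(side, paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_min", "conc_pM")
  if (!all(need %in% names(df)))
    stop("CSV must have columns time_min and conc_pM; got: ",
         paste(names(df), collapse = ", "))
  df$time_min <- suppressWarnings(as.numeric(as.character(df$time_min)))
  df$conc_pM <- suppressWarnings(as.numeric(as.character(df$conc_pM)))
  bad <- which(!is.finite(df$time_min) | !is.finite(df$conc_pM))
  if (length(bad))
    stop("malformed CSV row ", bad[1], " in ", path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  truth <- side$truth
  if (!is.null(truth) && !is.null(truth$n1))
    truth <- do.call(test_input_params, as.list(truth))
  er_dataset(df$time_min, df$conc_pM,
             timescale = side$timescale %||% "long",
             dose_mg = side$dose_mg %||% NA_real_,
             bodyweight_kg = side$bodyweight_kg %||% 90,
             truth = truth,
             meta = side$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
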