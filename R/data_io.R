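#' Moving-average lag transformation
#'
#' Computes, for each day, the arithmetic mean of a daily series over the
#' current day and the `max_lag` preceding days (a "lag 0-`max_lag`"
#' exposure in the air-pollution time-series convention).  The first
#' `max_lag` positions have incomplete windows and are returned as `NA`.
#'
#' @param x numeric vector, one value per consecutive day.
#' @param max_lag non-negative integer; the window extends `max_lag` days
#'   into the past, so the window width is `max_lag + 1`.
#' @return numeric vector of `length(x)`, with `NA` in the first `max_lag`
#'   positions.
#' @examples
#' lagged_mean(c(10, 30, 50, 70), 1)   # NA 20 40 60
#' @export
lagged_mean <- function(x, max_lag) {
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 0 ||
      max_lag != round(max_lag)) {
    stop("'max_lag' must be a single non-negative integer")
  }
  max_lag <- as.integer(max_lag)
  n <- length(x)
  if (max_lag >= n) {
    stop("'max_lag' (", max_lag, ") must be smaller than the series length (",
         n, ")")
  }
  if (max_lag == 0L) return(as.numeric(x))
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  idx <- (max_lag + 1L):n
  out[idx] <- (cs[idx + 1L] - cs[idx - max_lag]) / (max_lag + 1)
  out
}

# canonical column names of the daily CSV dialect
.gpsdrf_columns <- c(
  date = "date", pm10 = "pm10", temp = "temp", humidity = "humidity",
  holiday = "holiday", influenza = "influenza",
  deaths_natural = "deaths_natural", deaths_cvd = "deaths_cvd",
  deaths_resp = "deaths_resp"
)

#' Causes of death tracked by the package
#' @return character vector `c("natural", "cvd", "resp")`.
#' @export
death_causes <- function() c("natural", "cvd", "resp")

#' Build a study time series from a daily data frame
#'
#' Validates a per-day table (one row per consecutive calendar day) and
#' attaches the derived analysis variables: the lag 0-1 exposure
#' `pm10_lag01` and the lag 0-3 mean temperature `temp_lag03`.  Days whose
#' lag windows are incomplete are retained in the table but flagged `NA` in
#' the derived columns and excluded from all model fitting.
#'
#' @param data data.frame with columns `date` (Date or ISO-8601 character),
#'   `pm10`, `temp`, `humidity`, `holiday`, `influenza`, `deaths_natural`,
#'   `deaths_cvd`, `deaths_resp`.
#' @param exposure_lagged logical; if `FALSE` (default) the `pm10` column
#'   holds raw daily concentrations and the analysis exposure is the mean of
#'   the current and previous day.  If `TRUE` the column is taken to be an
#'   already-smoothed lag 0-1 exposure and is used as-is.
#' @return an object of class `study_series`: the daily data.frame with the
#'   derived columns and attributes `exposure_lagged` and `n_analysis`.
#' @export
study_series <- function(data, exposure_lagged = FALSE) {
  req <- .gpsdrf_columns
  missing_cols <- setdiff(unname(req), names(data))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[, unname(req)]
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable values in 'date'")
  if (is.unsorted(data$date, strictly = FALSE)) {
    stop("dates must be sorted ascending")
  }
  d <- diff(as.integer(data$date))
  if (any(d == 0L)) stop("duplicated dates in input")
  if (any(d > 1L)) {
    stop("gapped dates in input (first gap after ",
         format(data$date[which(d > 1L)[1L]]),
         "); lagged variables would mix non-adjacent days")
  }
  for (cc in c("deaths_natural", "deaths_cvd", "deaths_resp")) {
    y <- data[[cc]]
    if (any(!is.finite(y)) || any(y < 0) || any(y != round(y))) {
      stop("'", cc, "' must contain non-negative integer counts")
    }
  }
  if (any(!is.finite(data$pm10)) || any(data$pm10 < 0)) {
    stop("'pm10' must be non-negative and finite")
  }
  if (any(!is.finite(data$humidity)) || any(data$humidity < 0) ||
      any(data$humidity > 100)) {
    stop("'humidity' must lie in [0, 100]")
  }
  for (cc in c("holiday", "influenza")) {
    if (!all(data[[cc]] %in% c(0, 1))) stop("'", cc, "' must be 0/1")
  }

  data$pm10_lag01 <- if (exposure_lagged) as.numeric(data$pm10) else
    lagged_mean(data$pm10, 1L)
  data$temp_lag03 <- lagged_mean(data$temp, 3L)

  structure(data,
            exposure_lagged = exposure_lagged,
            n_analysis = sum(stats::complete.cases(
              data[, c("pm10_lag01", "temp_lag03")])),
            class = c("study_series", "data.frame"))
}

# indices of days with complete lag windows (the analysis set)
analysis_rows <- function(series) {
  which(!is.na(series$pm10_lag01) & !is.na(series$temp_lag03))
}

#' Extract the analysis table of a study series
#'
#' Returns only the days with complete lag windows, i.e. the rows actually
#' used by model fitting, together with the derived exposure and lagged
#' temperature.
#'
#' @param series a `study_series`.
#' @return data.frame of analysable days.
#' @export
analysis_table <- function(series) {
  stopifnot(inherits(series, "study_series"))
  as.data.frame(series)[analysis_rows(series), , drop = FALSE]
}

#' @export
print.study_series <- function(x, ...) {
  cat("Study time series:", nrow(x), "days (",
      format(min(x$date)), "to", format(max(x$date)), ")\n")
  cat("  analysable days (complete lag windows):",
      attr(x, "n_analysis"), "\n")
  cat("  exposure column treated as",
      if (isTRUE(attr(x, "exposure_lagged"))) "pre-computed lag 0-1"
      else "raw daily concentration", "\n")
  z <- x$pm10_lag01
  cat(sprintf("  lag 0-1 exposure: mean %.1f, sd %.1f, max %.1f\n",
              mean(z, na.rm = TRUE), stats::sd(z, na.rm = TRUE),
              max(z, na.rm = TRUE)))
  invisible(x)
}

#' Read a daily time series CSV
#'
#' Reads the package's CSV dialect (one row per consecutive day) and
#' constructs a validated [study_series()].  Non-default column names are
#' remapped through `column_map`.
#'
#' @param path file path of the CSV.
#' @param column_map optional named character vector mapping canonical names
#'   (e.g. `pm10`) to the names used in the file.
#' @param exposure_lagged see [study_series()].
#' @return a `study_series`.
#' @export
read_pm_series <- function(path, column_map = NULL, exposure_lagged = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad)) {
      stop("column_map refers to absent column(s): ",
           paste(bad, collapse = ", "))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  study_series(raw, exposure_lagged = exposure_lagged)
}

#' Write a study series to CSV
#'
#' Writes the full daily table including the derived `pm10_lag01` and
#' `temp_lag03` columns.  Reading the file back with [read_pm_series()]
#' (with the same `exposure_lagged` flag) reproduces the derived values.
#'
#' @param series a `study_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pm_series <- function(series, path) {
  stopifnot(inherits(series, "study_series"))
  df <- as.data.frame(series)
  df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
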