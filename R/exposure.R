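#' Exposure-model covariate design
#'
#' Builds the covariate matrix of the log-normal exposure model on the
#' analysable days of a study series: six day-of-week indicators (Monday
#' reference), holiday and influenza indicators, a linear calendar spline
#' (default 5 df per year, equally spaced knots) for seasonality and trend,
#' a cubic spline of mean temperature at lag 0-3 (default 5 df, knots at the
#' quantiles), linear and quadratic relative humidity, and a July-August
#' indicator for the summer population dip.
#'
#' @param series a `study_series`.
#' @param df_per_year calendar-spline degrees of freedom per year.
#' @param temp_df temperature-spline degrees of freedom.
#' @return numeric matrix (no intercept column) with one row per analysable
#'   day.
#' @export
exposure_design <- function(series, df_per_year = 5L, temp_df = 5L) {
  stopifnot(inherits(series, "study_series"))
  idx <- analysis_rows(series)
  df <- as.data.frame(series)[idx, , drop = FALSE]

  dow <- factor(format(df$date, "%u"), levels = as.character(1:7))
  dow_mat <- stats::model.matrix(~dow)[, -1L, drop = FALSE]
  colnames(dow_mat) <- c("tue", "wed", "thu", "fri", "sat", "sun")

  day_index <- as.integer(df$date - min(series$date)) + 1L
  n_years <- nrow(series) / 365.25
  cal <- calendar_spline(day_index, df_per_year = df_per_year,
                         n_years = n_years)

  tsp <- cubic_quantile_spline(df$temp_lag03, df = temp_df)
  colnames(tsp) <- paste0("templag03_s", seq_len(ncol(tsp)))

  hum <- cbind(humidity = df$humidity, humidity2 = df$humidity^2)
  julaug <- as.numeric(format(df$date, "%m") %in% c("07", "08"))

  X <- cbind(dow_mat, holiday = df$holiday, influenza = df$influenza,
             cal, tsp, hum, julaug = julaug)
  rownames(X) <- NULL
  X
}

#' Fit the log-normal exposure model
#'
#' Ordinary least squares of the log lag 0-1 exposure on the covariate
#' design of [exposure_design()], giving the generalized propensity score
#' model: `log(Z_i) ~ N(alpha0 + alphaX' X_i, sigmaZ)`.  The scale is the
#' maximum-likelihood estimate (residual sum of squares divided by N).
#'
#' @param series a `study_series` with strictly positive exposures.
#' @param design optional pre-built covariate matrix (rows must match the
#'   analysable days); built from `series` when `NULL`.
#' @return object of class `gps_exposure`: list with `alpha0`, `alphaX`,
#'   `sigma`, `fitted` (linear predictor of the log exposure), `logZ`, `X`,
#'   and `n`.
#' @export
fit_exposure <- function(series, design = NULL) {
  stopifnot(inherits(series, "study_series"))
  idx <- analysis_rows(series)
  Z <- series$pm10_lag01[idx]
  if (any(Z <= 0)) {
    stop("all exposures must be strictly positive to fit the log-normal ",
         "exposure model")
  }
  X <- if (is.null(design)) exposure_design(series) else design
  if (nrow(X) != length(Z)) stop("design rows do not match analysable days")
  X1 <- cbind("(Intercept)" = 1, X)
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    drop_cols <- colnames(X1)[qx$pivot[(qx$rank + 1L):ncol(X1)]]
    stop("exposure design is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  logZ <- log(Z)
  coefs <- qr.coef(qx, logZ)
  fitted <- drop(X1 %*% coefs)
  res <- logZ - fitted
  n <- length(Z)
  structure(list(alpha0 = coefs[1L], alphaX = coefs[-1L],
                 sigma = sqrt(sum(res^2) / n),
                 fitted = fitted, logZ = logZ, X = X, n = n),
            class = "gps_exposure")
}

#' @export
print.gps_exposure <- function(x, ...) {
  cat("Log-normal exposure model (GPS)\n")
  cat("  days:", x$n, "  covariates:", length(x$alphaX), "\n")
  cat(sprintf("  sigma_Z (MLE): %.4f\n", x$sigma))
  cat(sprintf("  R-squared of log exposure: %.3f\n",
              1 - sum((x$logZ - x$fitted)^2) /
                sum((x$logZ - mean(x$logZ))^2)))
  invisible(x)
}

#' @export
coef.gps_exposure <- function(object, ...) {
  c("(Intercept)" = unname(object$alpha0), object$alphaX)
}

#' Generalized propensity score density
#'
#' Evaluates the GPS `r(z; x)`: the normal density of `log(z)` at the
#' exposure model's conditional mean and scale.  The conditional mean can be
#' supplied directly (`mu`) or computed from a covariate row aligned with
#' the training design (`x_row`).
#'
#' @param fit a `gps_exposure`.
#' @param z positive exposure value(s).
#' @param x_row covariate vector (one day, no intercept) or matrix.
#' @param mu alternatively, precomputed conditional mean(s) of the log
#'   exposure; defaults to the training fitted values.
#' @return density value(s), strictly positive.
#' @export
gps_density <- function(fit, z, x_row = NULL, mu = NULL) {
  stopifnot(inherits(fit, "gps_exposure"))
  if (any(z <= 0)) stop("'z' must be strictly positive")
  if (is.null(mu)) {
    mu <- if (is.null(x_row)) fit$fitted else {
      xr <- if (is.null(dim(x_row))) matrix(x_row, nrow = 1L) else x_row
      fit$alpha0 + drop(xr %*% fit$alphaX)
    }
  }
  stats::dnorm(log(z), mean = mu, sd = fit$sigma)
}

#' Actual generalized propensity score
#'
#' The GPS of each analysable day evaluated at that day's observed exposure,
#' `R_i = r(Z_i; X_i)`.
#'
#' @param fit a `gps_exposure`.
#' @return numeric vector of strictly positive densities, one per
#'   analysable day.
#' @export
actual_gps <- function(fit) {
  stopifnot(inherits(fit, "gps_exposure"))
  stats::dnorm(fit$logZ, mean = fit$fitted, sd = fit$sigma)
}
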