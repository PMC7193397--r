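#' Fit a GPS dose-response model
#'
#' The package's main fitting function.  Chains the two working models of
#' the semiparametric GPS approach on the analysable days of a study
#' series: (1) a log-normal model of the lag 0-1 exposure given calendar
#' and meteorological covariates, yielding the generalized propensity score
#' (GPS); (2) a penalized quasi-Poisson model of the daily death count for
#' one cause on a bivariate thin-plate radial spline in the exposure and
#' the actual GPS, with smoothing selected by GCV.  The fitted object
#' supports prediction of potential outcomes `Yhat_i(z)` and hence the
#' average dose-response function and attributable-death estimands.
#'
#' @param series a [study_series()].
#' @param cause one of `"natural"`, `"cvd"`, `"resp"`.
#' @param K number of radial knots of the outcome smoother.
#' @param lambda optional fixed smoothing parameter (GCV selection when
#'   `NULL`).
#' @param ... further arguments passed to [fit_outcome()].
#' @return object of class `gps_drf`: list with components `exposure`
#'   (`gps_exposure`), `outcome` (`gps_outcome`), `series`, `cause`, `Z`,
#'   `y`, `R` and `call`.
#' @seealso [adrf()], [attributable_deaths()], [dad()], [balance_report()],
#'   [gps_boot()]
#' @examples
#' sim <- simulate_pm_study(n_days = 400, seed = 1)
#' fit <- gps_drf(sim$series, cause = "natural", K = 20)
#' fit
#' @export
gps_drf <- function(series, cause = c("natural", "cvd", "resp"), K = 50L,
                    lambda = NULL, ...) {
  cause <- match.arg(cause)
  stopifnot(inherits(series, "study_series"))
  idx <- analysis_rows(series)
  Z <- series$pm10_lag01[idx]
  y <- series[[paste0("deaths_", cause)]][idx]

  exposure <- fit_exposure(series)
  R <- actual_gps(exposure)
  outcome <- fit_outcome(y, Z, R, K = K, lambda = lambda, ...)

  structure(list(exposure = exposure, outcome = outcome, series = series,
                 cause = cause, Z = Z, y = y, R = R,
                 call = match.call()),
            class = "gps_drf")
}

#' Predict potential outcomes at a counterfactual exposure
#'
#' For each analysable day `i`, evaluates the GPS at the counterfactual
#' exposure `z` (`r(z; X_i)`, using day `i`'s covariates) and returns the
#' predicted potential outcome `Yhat_i(z) = exp(s(z, r(z; X_i)))`.
#' Standardized coordinates outside the training cloud are clamped into
#' `[0, 1]`; the clamp count is reported as an attribute.
#'
#' @param fit a `gps_drf`.
#' @param z a single positive exposure value.
#' @return numeric vector of length N with attribute `n_clamped`.
#' @export
predict_potential <- function(fit, z) {
  stopifnot(inherits(fit, "gps_drf"))
  if (length(z) != 1L || z <= 0) stop("'z' must be a single positive value")
  r_z <- gps_density(fit$exposure, z)
  Xp <- eval_penalized_basis(fit$outcome$basis, rep(z, length(r_z)), r_z)
  out <- exp(drop(Xp %*% fit$outcome$beta))
  attr(out, "n_clamped") <- attr(Xp, "n_clamped")
  out
}

#' @export
print.gps_drf <- function(x, ...) {
  cat("GPS dose-response fit -", x$cause, "deaths\n")
  cat("  analysable days:", length(x$y), "\n")
  cat(sprintf("  exposure model: sigma_Z = %.4f\n", x$exposure$sigma))
  cat(sprintf("  outcome model: lambda = %.4g, edf = %.2f, dispersion = %.3f\n",
              x$outcome$lambda, x$outcome$edf, x$outcome$dispersion))
  invisible(x)
}

#' @export
summary.gps_drf <- function(object, ...) {
  z <- object$Z
  out <- list(
    cause = object$cause,
    n = length(object$y),
    exposure_sigma = object$exposure$sigma,
    exposure_r2 = 1 - sum((object$exposure$logZ - object$exposure$fitted)^2) /
      sum((object$exposure$logZ - mean(object$exposure$logZ))^2),
    lambda = object$outcome$lambda,
    edf = object$outcome$edf,
    dispersion = object$outcome$dispersion,
    deviance = object$outcome$deviance,
    exposure_range = range(z),
    mean_count = mean(object$y)
  )
  class(out) <- "summary.gps_drf"
  out
}

#' @export
print.summary.gps_drf <- function(x, ...) {
  cat("GPS dose-response model -", x$cause, "deaths\n\n")
  cat(sprintf("Days: %d   mean daily count: %.2f\n", x$n, x$mean_count))
  cat(sprintf("Exposure (lag 0-1) range: %.1f to %.1f ug/m3\n",
              x$exposure_range[1L], x$exposure_range[2L]))
  cat("\nExposure model (log-normal GPS):\n")
  cat(sprintf("  sigma_Z = %.4f,  R2(log Z) = %.3f\n",
              x$exposure_sigma, x$exposure_r2))
  cat("\nOutcome model (penalized quasi-Poisson):\n")
  cat(sprintf("  lambda = %.4g,  edf = %.2f\n", x$lambda, x$edf))
  cat(sprintf("  deviance = %.1f,  dispersion = %.3f\n",
              x$deviance, x$dispersion))
  invisible(x)
}

#' @export
coef.gps_drf <- function(object, model = c("outcome", "exposure"), ...) {
  model <- match.arg(model)
  if (model == "outcome") {
    stats::setNames(object$outcome$beta, colnames(object$outcome$basis$X))
  } else {
    coef(object$exposure)
  }
}

#' @export
fitted.gps_drf <- function(object, ...) object$outcome$fitted

#' @export
residuals.gps_drf <- function(object,
                              type = c("response", "pearson", "deviance"),
                              ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$outcome$fitted
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = sign(y - mu) *
           sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))))
}

#' Predict method for GPS dose-response fits
#'
#' `type = "adrf"` returns the average dose-response function over the
#' requested grid; `type = "potential"` returns the full N x length(z)
#' matrix of per-day potential outcomes.
#'
#' @param object a `gps_drf`.
#' @param z exposure value(s); defaults to a 100-point grid over the
#'   observed exposure range.
#' @param type `"adrf"` or `"potential"`.
#' @param ... unused.
#' @export
predict.gps_drf <- function(object, z = NULL,
                            type = c("adrf", "potential"), ...) {
  type <- match.arg(type)
  if (is.null(z)) z <- seq(min(object$Z), max(object$Z), length.out = 100L)
  mat <- vapply(z, function(zz) as.numeric(predict_potential(object, zz)),
                numeric(length(object$y)))
  if (type == "potential") return(mat)
  stats::setNames(colMeans(mat), format(z, trim = TRUE))
}

#' Simulate daily counts from a fitted GPS dose-response model
#'
#' Draws Poisson counts at the fitted means (parametric simulation from the
#' point estimates; the quasi-Poisson dispersion is not inflated).
#'
#' @param object a `gps_drf`.
#' @param nsim number of simulated series.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of counts.
#' @export
simulate.gps_drf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$outcome$fitted
  out <- as.data.frame(replicate(nsim, stats::rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the estimated average dose-response function
#'
#' @param x a `gps_drf`.
#' @param z_grid exposure grid (defaults to 100 points over the observed
#'   range).
#' @param show_data add the observed (exposure, count) scatter.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gps_drf <- function(x, z_grid = NULL, show_data = TRUE, ...) {
  if (is.null(z_grid)) z_grid <- seq(min(x$Z), max(x$Z), length.out = 100L)
  mu <- predict(x, z = z_grid, type = "adrf")
  if (show_data) {
    graphics::plot(x$Z, x$y, pch = 16, cex = 0.4, col = "grey70",
                   xlab = expression(paste("PM10 lag 0-1 (", mu, "g/", m^3,
                                           ")")),
                   ylab = paste("daily", x$cause, "deaths"), ...)
    graphics::lines(z_grid, mu, lwd = 2, col = "steelblue4")
  } else {
    graphics::plot(z_grid, mu, type = "l", lwd = 2, col = "steelblue4",
                   xlab = expression(paste("PM10 lag 0-1 (", mu, "g/", m^3,
                                           ")")),
                   ylab = "average dose-response", ...)
  }
  invisible(mu)
}
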