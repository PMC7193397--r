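#' Nonparametric bootstrap for GPS causal estimands
#'
#' Resamples analysable days independently with replacement (lagged
#' variables stay attached to their day), refits the exposure model,
#' recomputes the actual GPS, refits the outcome model, and re-evaluates a
#' user statistic on each replicate.  Confidence intervals are percentile
#' intervals (5th and 95th percentiles for the default 90% level).
#' Replicates whose refit fails are dropped and counted; more than 5%
#' failures aborts with an error.
#'
#' @param fit a [gps_drf()] fit.
#' @param statistic function of a `gps_drf` fit returning a numeric vector
#'   (e.g. `function(f) attributable_deaths(f, 40)$point`).
#' @param B number of bootstrap replicates (at least 50).
#' @param seed RNG seed for the resampling (and anything stochastic inside
#'   `statistic`).
#' @param refit_lambda `"gcv"` re-selects the smoothing parameter on every
#'   replicate (full uncertainty propagation); `"fixed"` freezes it at the
#'   original fit's value.
#' @param level confidence level (default 0.90).
#' @return object of class `gps_boot`: list with `t0` (original statistic),
#'   `reps` (B x q matrix), `ci_low`, `ci_high`, `n_fail`, `B`, `level`.
#' @export
gps_boot <- function(fit, statistic, B = 1000L, seed = NULL,
                     refit_lambda = c("gcv", "fixed"), level = 0.90) {
  stopifnot(inherits(fit, "gps_drf"), is.function(statistic))
  if (B < 50L) stop("'B' must be at least 50")
  refit_lambda <- match.arg(refit_lambda)
  if (!is.null(seed)) set.seed(seed)

  t0 <- statistic(fit)
  q <- length(t0)
  N <- length(fit$y)
  Xexp <- fit$exposure$X
  df_full <- analysis_table(fit$series)
  K <- nrow(fit$outcome$basis$knots)
  lam_fixed <- if (refit_lambda == "fixed") fit$outcome$lambda else NULL

  reps <- matrix(NA_real_, nrow = B, ncol = q)
  n_fail <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(N, N, replace = TRUE)
    rb <- tryCatch({
      fb <- refit_gps_drf(fit, df_full, Xexp, idx, K, lam_fixed)
      as.numeric(statistic(fb))
    }, error = function(e) NULL)
    if (is.null(rb) || length(rb) != q || anyNA(rb)) {
      n_fail <- n_fail + 1L
    } else {
      reps[b, ] <- rb
    }
  }
  if (n_fail > 0.05 * B) {
    stop("bootstrap unstable: ", n_fail, " of ", B, " replicates failed")
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - level) / 2
  ci_low <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                  probs = alpha, names = FALSE)
  ci_high <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
                   probs = 1 - alpha, names = FALSE)
  structure(list(t0 = t0, reps = reps[ok, , drop = FALSE],
                 ci_low = ci_low, ci_high = ci_high,
                 n_fail = n_fail, B = B, level = level,
                 refit_lambda = refit_lambda),
            class = "gps_boot")
}

# one bootstrap replicate: re-estimate both working models on resampled days
refit_gps_drf <- function(fit, df_full, Xexp, idx, K, lam_fixed) {
  Xb <- Xexp[idx, , drop = FALSE]
  Zb <- fit$Z[idx]
  yb <- fit$y[idx]
  logZb <- log(Zb)
  X1 <- cbind(1, Xb)
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) stop("rank-deficient resampled exposure design")
  coefs <- qr.coef(qx, logZb)
  mu_b <- drop(X1 %*% coefs)
  sigma_b <- sqrt(sum((logZb - mu_b)^2) / length(Zb))
  exp_b <- structure(list(alpha0 = coefs[1L], alphaX = coefs[-1L],
                          sigma = sigma_b, fitted = mu_b, logZb = logZb,
                          logZ = logZb, X = Xb, n = length(Zb)),
                     class = "gps_exposure")
  Rb <- stats::dnorm(logZb, mu_b, sigma_b)
  out_b <- fit_outcome(yb, Zb, Rb, K = K, lambda = lam_fixed)
  series_b <- df_full[idx, , drop = FALSE]
  class(series_b) <- c("study_series", "data.frame")
  attr(series_b, "exposure_lagged") <- TRUE
  attr(series_b, "n_analysis") <- length(idx)
  structure(list(exposure = exp_b, outcome = out_b, series = series_b,
                 cause = fit$cause, Z = Zb, y = yb, R = Rb,
                 call = fit$call),
            class = "gps_drf")
}

#' @export
print.gps_boot <- function(x, ...) {
  cat(sprintf("Bootstrap (%d replicates, %d failed, lambda %s)\n",
              x$B, x$n_fail, x$refit_lambda))
  for (j in seq_along(x$t0)) {
    cat(sprintf("  estimate %.2f   %.0f%% CI (%.2f, %.2f)\n",
                x$t0[j], 100 * x$level, x$ci_low[j], x$ci_high[j]))
  }
  invisible(x)
}
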