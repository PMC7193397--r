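#' Configuration of the synthetic study generator
#'
#' Defaults emulate a four-year Mediterranean-climate urban time series:
#' seasonal temperature (annual mean 14.5 degrees C, amplitude 10, iid
#' noise sd 3), seasonal humidity, calendar holiday / influenza / summer
#' indicators, a conditionally log-normal lag 0-1 exposure confounded by
#' season and temperature and calibrated to a marginal mean of about
#' 52.5 ug/m3 with sd about 33, and Poisson death counts for three causes
#' (means about 28.0 natural, 10.3 cardiovascular, 2.5 respiratory) with a
#' known saturating dose-response `g(z) = gamma * log(1 + z / tau)` plus
#' cold/heat and seasonal baseline mortality loadings.
#'
#' @param n_days number of days (default 1461, four years).
#' @param temp_mean,temp_amp,temp_sd temperature sinusoid parameters
#'   (degrees C).
#' @param hum_mean,hum_amp,hum_sd humidity parameters (%, clamped to
#'   `[20, 100]`).
#' @param exp_seasonal,exp_temp,exp_weekend log-exposure loadings on the
#'   winter-peaking seasonal cosine, the standardized lag 0-3 temperature,
#'   and a weekend indicator.
#' @param sigma_z residual sd of the log exposure.
#' @param exp_mean target marginal mean of the exposure (ug/m3).
#' @param count_means named target mean daily counts per cause.
#' @param gamma named dose-response slopes per cause.
#' @param tau dose-response saturation scale (ug/m3).
#' @param out_seasonal baseline-mortality seasonal (winter) loading.
#' @param temp_u curvature of the U-shaped temperature-mortality loading
#'   (per squared degree C around `temp_ref`).
#' @param temp_ref minimum-mortality temperature (degrees C).
#' @param interaction exposure-by-temperature effect-modification
#'   coefficient (per degree C of lag 0-3 temperature above its mean;
#'   default 0).
#' @param overdispersion variance of a mean-one gamma frailty multiplying
#'   the count means (0 = plain Poisson).
#' @return list of class `pm_sim_config`.
#' @export
pm_sim_config <- function(n_days = 1461L,
                          temp_mean = 14.5, temp_amp = 10, temp_sd = 3,
                          hum_mean = 70, hum_amp = 12, hum_sd = 8,
                          exp_seasonal = 0.32, exp_temp = -0.06,
                          exp_weekend = -0.08, sigma_z = 0.48,
                          exp_mean = 52.5,
                          count_means = c(natural = 28.0, cvd = 10.3,
                                          resp = 2.5),
                          gamma = c(natural = 0.18, cvd = 0.21,
                                    resp = 0.35),
                          tau = 20,
                          out_seasonal = 0.08, temp_u = 6e-4,
                          temp_ref = 20, interaction = 0,
                          overdispersion = 0) {
  stopifnot(n_days >= 60, sigma_z > 0, tau > 0, all(gamma >= 0),
            overdispersion >= 0, temp_sd >= 0)
  structure(as.list(environment()), class = "pm_sim_config")
}

# fixed-date public holidays of the emulated calendar
.holiday_md <- c("01-01", "01-06", "04-25", "05-01", "06-02", "08-15",
                 "11-01", "12-08", "12-25", "12-26")

#' Generate a synthetic study with known ground truth
#'
#' Draws a daily time series from the process described in
#' [pm_sim_config()].  The exposure written to the series is the lag 0-1
#' value itself (`exposure_lagged = TRUE`), drawn conditionally log-normal
#' with a mean that is exactly linear in the package's exposure-model
#' covariate design — so the exposure-model coefficients have an exact
#' known truth.  Counts are Poisson (optionally gamma-frailty
#' overdispersed) with means
#' `exp(b0 + baseline_i + (1 + interaction * tdev_i) * g(Z_i))`,
#' and the returned truth object carries the exact per-day expected
#' potential outcomes, hence closed-form true aDRF, AD and DAD.
#'
#' @param n_days number of days (overrides `config`).
#' @param seed RNG seed; every random draw derives from it.
#' @param config a [pm_sim_config()].
#' @return list with elements `series` (a [study_series()]), `truth`
#'   (class `pm_sim_truth`) and `config`.
#' @export
simulate_pm_study <- function(n_days = NULL, seed = 1L,
                              config = pm_sim_config()) {
  stopifnot(inherits(config, "pm_sim_config"))
  if (!is.null(n_days)) config$n_days <- as.integer(n_days)
  n <- config$n_days
  set.seed(seed)

  dates <- seq(as.Date("2003-01-01"), by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  seas <- cos(2 * pi * (doy - 15) / 365.25)   # peaks mid-January
  temp <- config$temp_mean - config$temp_amp * seas +
    stats::rnorm(n, 0, config$temp_sd)
  humidity <- config$hum_mean + config$hum_amp * seas +
    stats::rnorm(n, 0, config$hum_sd)
  humidity <- pmin(pmax(humidity, 20), 100)
  md <- format(dates, "%m-%d")
  holiday <- as.numeric(md %in% .holiday_md)
  influenza <- as.numeric(doy >= 5 & doy <= 60)
  weekend <- as.numeric(format(dates, "%u") %in% c("6", "7"))

  # skeleton series (placeholder exposure) to build the covariate design
  df <- data.frame(date = dates, pm10 = 50, temp = temp,
                   humidity = humidity, holiday = holiday,
                   influenza = influenza, deaths_natural = 0L,
                   deaths_cvd = 0L, deaths_resp = 0L)
  skel <- study_series(df, exposure_lagged = TRUE)
  idx <- analysis_rows(skel)
  X <- exposure_design(skel)
  N <- length(idx)

  # target log-exposure surface, projected onto the design so that the
  # conditional mean is exactly linear in the model covariates
  tl <- skel$temp_lag03[idx]
  target <- config$exp_seasonal * seas[idx] +
    config$exp_temp * (tl - config$temp_mean) / 8.4 +
    config$exp_weekend * weekend[idx]
  X1 <- cbind(1, X)
  alpha <- qr.coef(qr(X1), target)
  mu_log <- drop(X1 %*% alpha)
  shift <- log(config$exp_mean) -
    log(mean(exp(mu_log + config$sigma_z^2 / 2)))
  alpha[1L] <- alpha[1L] + shift
  mu_log <- mu_log + shift

  Z <- exp(stats::rnorm(N, mu_log, config$sigma_z))
  pm10 <- numeric(n)
  pm10[idx] <- Z
  pm10[-idx] <- exp(stats::rnorm(n - N, mu_log[1L], config$sigma_z))

  # outcome process
  tdev <- tl - config$temp_mean
  g <- function(z, cause) {
    config$gamma[[cause]] * log(1 + z / config$tau)
  }
  baseline <- config$out_seasonal * seas[idx] +
    config$temp_u * (temp[idx] - config$temp_ref)^2
  baseline_pre <- config$out_seasonal * seas[-idx] +
    config$temp_u * (temp[-idx] - config$temp_ref)^2
  causes <- death_causes()
  b0 <- lam0 <- stats::setNames(vector("list", 3L), causes)
  counts <- matrix(0L, nrow = n, ncol = 3L,
                   dimnames = list(NULL, causes))
  for (cc in causes) {
    gz <- (1 + config$interaction * tdev) * g(Z, cc)
    b0[[cc]] <- log(config$count_means[[cc]]) -
      log(mean(exp(baseline + gz)))
    lam <- exp(b0[[cc]] + baseline + gz)
    lam_pre <- exp(b0[[cc]] + baseline_pre + g(pm10[-idx], cc))
    lam_all <- numeric(n)
    lam_all[idx] <- lam
    lam_all[-idx] <- lam_pre
    if (config$overdispersion > 0) {
      sh <- 1 / config$overdispersion
      lam_all <- lam_all * stats::rgamma(n, shape = sh, rate = sh)
    }
    counts[, cc] <- stats::rpois(n, lam_all)
    lam0[[cc]] <- exp(b0[[cc]] + baseline)   # expected count at g = 0
  }
  df$pm10 <- pm10
  df$deaths_natural <- counts[, "natural"]
  df$deaths_cvd <- counts[, "cvd"]
  df$deaths_resp <- counts[, "resp"]
  series <- study_series(df, exposure_lagged = TRUE)

  truth <- structure(list(
    alpha = stats::setNames(alpha, c("(Intercept)", colnames(X))),
    sigma_z = config$sigma_z,
    mu_log = mu_log,
    lam0 = lam0, tdev = tdev, Z = Z,
    gamma = config$gamma, tau = config$tau,
    interaction = config$interaction,
    config = config), class = "pm_sim_truth")

  list(series = series, truth = truth, config = config)
}

# exact expected potential outcome E[Y_i(z)] for every analysable day
truth_ey <- function(truth, z, cause) {
  gz <- truth$gamma[[cause]] * log(1 + z / truth$tau)
  truth$lam0[[cause]] * exp((1 + truth$interaction * truth$tdev) * gz)
}

#' True average dose-response function of a synthetic study
#'
#' @param truth a `pm_sim_truth`.
#' @param z exposure value(s).
#' @param cause cause of death.
#' @return the exact `mu(z)` (average over days of the expected potential
#'   outcome), vectorized over `z`.
#' @export
true_adrf <- function(truth, z, cause = "natural") {
  stopifnot(inherits(truth, "pm_sim_truth"))
  vapply(z, function(zz) mean(truth_ey(truth, zz, cause)), numeric(1L))
}

#' True attributable deaths of a synthetic study
#'
#' Exact `AD(z*)` computed from expected (not sampled) potential outcomes:
#' `sum over days with Z_i > z* of (E[Y_i(Z_i)] - E[Y_i(z*)])`.
#'
#' @inheritParams true_adrf
#' @param z_star threshold in `(0, max(Z)]`.
#' @export
true_ad <- function(truth, z_star, cause = "natural") {
  stopifnot(inherits(truth, "pm_sim_truth"))
  if (z_star <= 0 || z_star > max(truth$Z)) {
    stop("'z_star' must lie in (0, max observed exposure]")
  }
  treated <- truth$Z > z_star
  if (!any(treated)) return(0)
  gz <- truth$gamma[[cause]] * log(1 + truth$Z[treated] / truth$tau)
  ey_obs <- truth$lam0[[cause]][treated] *
    exp((1 + truth$interaction * truth$tdev[treated]) * gz)
  ey_cf <- truth_ey(truth, z_star, cause)[treated]
  sum(ey_obs - ey_cf)
}

#' True distributional attributable deaths of a synthetic study
#'
#' Exact `DAD(z*)` by enumeration of the empirical below-threshold exposure
#' distribution (no Monte Carlo).
#'
#' @inheritParams true_ad
#' @export
true_dad <- function(truth, z_star, cause = "natural") {
  stopifnot(inherits(truth, "pm_sim_truth"))
  if (z_star <= 0 || z_star > max(truth$Z)) {
    stop("'z_star' must lie in (0, max observed exposure]")
  }
  treated <- truth$Z > z_star
  support <- truth$Z[!treated]
  if (!any(treated) || !length(support)) {
    stop("DAD truth undefined: need days on both sides of z*")
  }
  gz <- truth$gamma[[cause]] * log(1 + truth$Z[treated] / truth$tau)
  ey_obs <- truth$lam0[[cause]][treated] *
    exp((1 + truth$interaction * truth$tdev[treated]) * gz)
  mean(vapply(support, function(v) {
    sum(ey_obs - truth_ey(truth, v, cause)[treated])
  }, numeric(1L)))
}

#' @export
print.pm_sim_truth <- function(x, ...) {
  cat("Synthetic study ground truth\n")
  cat(sprintf("  days: %d, sigma_Z = %.3f\n", length(x$Z), x$sigma_z))
  cat(sprintf("  dose-response g(z) = gamma log(1 + z/%.0f), gamma = %s\n",
              x$tau, paste(sprintf("%s %.2f", names(x$gamma), x$gamma),
                           collapse = ", ")))
  if (x$interaction != 0) {
    cat(sprintf("  temperature effect modification: %.3f per degree C\n",
                x$interaction))
  }
  invisible(x)
}
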