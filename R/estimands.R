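new_estimand <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "gps_estimand")
}

#' @export
print.gps_estimand <- function(x, ...) {
  cat("Causal estimand:", x$kind, "\n")
  if (x$kind %in% c("AD", "DAD")) {
    cat(sprintf("  threshold z* = %.1f ug/m3, treated days = %d\n",
                x$z_star, x$n_treated))
    cat(sprintf("  point estimate: %.1f deaths", x$point))
    if (!is.null(x$ci_low) && !is.na(x$ci_low)) {
      cat(sprintf("  (90%% CI %.1f, %.1f)", x$ci_low, x$ci_high))
    }
    cat("\n")
    if (!is.null(x$mc_se)) {
      cat(sprintf("  Monte-Carlo draws M = %d (MC SE %.2f)\n", x$M, x$mc_se))
    }
  } else {
    cat(sprintf("  grid of %d exposure values in [%.1f, %.1f]\n",
                length(x$grid), min(x$grid), max(x$grid)))
    cat(sprintf("  mean level %.2f, range %.2f to %.2f deaths/day\n",
                mean(x$point), min(x$point), max(x$point)))
    if (!is.null(x$n_subset)) cat("  subset days:", x$n_subset, "\n")
  }
  invisible(x)
}

#' Average dose-response function
#'
#' Estimates `mu(z) = (1/N) sum_i Yhat_i(z)` over an exposure grid: the
#' average daily death count had every day's exposure been set to `z`.
#'
#' @param fit a [gps_drf()] fit.
#' @param z_grid exposure grid; defaults to 100 equally spaced points over
#'   the observed exposure range.
#' @param subset optional logical vector (length N, over analysable days)
#'   or predicate function applied to the analysis table, defining the
#'   day subset of a conditional aDRF.
#' @return a `gps_estimand` with elements `grid`, `point`, `n_subset`,
#'   `n_clamped`.
#' @export
adrf <- function(fit, z_grid = NULL, subset = NULL) {
  stopifnot(inherits(fit, "gps_drf"))
  if (!is.null(z_grid) && length(z_grid) == 0L) {
    stop("'z_grid' must be non-empty")
  }
  if (is.null(z_grid)) {
    z_grid <- seq(min(fit$Z), max(fit$Z), length.out = 100L)
  }
  N <- length(fit$y)
  keep <- if (is.null(subset)) rep(TRUE, N) else if (is.function(subset)) {
    subset(analysis_table(fit$series))
  } else subset
  if (length(keep) != N) stop("'subset' length does not match analysis days")
  if (!any(keep)) stop("conditional aDRF subset is empty")
  point <- numeric(length(z_grid))
  clamped <- 0L
  for (j in seq_along(z_grid)) {
    yhat <- predict_potential(fit, z_grid[j])
    clamped <- clamped + attr(yhat, "n_clamped")
    point[j] <- mean(yhat[keep])
  }
  new_estimand("adrf", grid = z_grid, point = point,
               n_subset = sum(keep), n_clamped = clamped,
               cause = fit$cause)
}

#' Conditional aDRF by temperature category
#'
#' Splits days into low / medium / high mean lag 0-3 temperature
#' (boundaries 10 and 23 degrees C by default: `low <= 10 < medium <= 23 <
#' high`) and estimates the conditional average dose-response function in
#' each stratum.
#'
#' @param fit a `gps_drf`.
#' @param breaks two increasing temperature boundaries (degrees C).
#' @param z_grid exposure grid passed to [adrf()].
#' @return named list of three `gps_estimand`s (`low`, `medium`, `high`).
#' @export
adrf_by_temperature <- function(fit, breaks = c(10, 23), z_grid = NULL) {
  stopifnot(length(breaks) == 2L, breaks[1L] < breaks[2L])
  tl <- analysis_table(fit$series)$temp_lag03
  strata <- list(low = tl <= breaks[1L],
                 medium = tl > breaks[1L] & tl <= breaks[2L],
                 high = tl > breaks[2L])
  lapply(strata, function(keep) {
    if (!any(keep)) {
      stop("temperature stratum is empty for breaks ",
           paste(breaks, collapse = "/"))
    }
    adrf(fit, z_grid = z_grid, subset = keep)
  })
}

#' Attributable deaths under a fixed counterfactual threshold
#'
#' `AD(z*) = sum over days with Z_i > z* of (Y_i - Yhat_i(z*))`: the excess
#' observed deaths on above-threshold days relative to the counterfactual
#' in which those days' exposure is set exactly to `z*`.
#'
#' @param fit a `gps_drf`.
#' @param z_star positive counterfactual threshold (ug/m3).
#' @return a `gps_estimand` with `point`, `z_star`, `n_treated`.
#' @export
attributable_deaths <- function(fit, z_star) {
  stopifnot(inherits(fit, "gps_drf"))
  if (length(z_star) != 1L || z_star <= 0) {
    stop("'z_star' must be a single positive threshold")
  }
  treated <- fit$Z > z_star
  if (!any(treated)) {
    warning("no days exceed z* = ", z_star, "; AD is 0")
    return(new_estimand("AD", z_star = z_star, point = 0,
                        n_treated = 0L, cause = fit$cause))
  }
  yhat <- predict_potential(fit, z_star)
  new_estimand("AD", z_star = z_star,
               point = sum(fit$y[treated] - yhat[treated]),
               n_treated = sum(treated), cause = fit$cause)
}

#' Distributional attributable deaths
#'
#' `DAD(z*)` replaces above-threshold exposures with draws from the
#' empirical exposure distribution of the below-threshold days `p*(z)` and
#' integrates the attributable-death sum over that distribution.  The
#' integral is evaluated either by Monte Carlo (`M` uniform draws from the
#' observed below-threshold exposures) or exactly, by enumerating the
#' finite support of `p*`.
#'
#' @param fit a `gps_drf`.
#' @param z_star positive threshold; there must be days on both sides.
#' @param M number of Monte-Carlo draws (default 1000).
#' @param seed optional RNG seed for the draws.
#' @param exact if `TRUE`, average over all below-threshold days instead of
#'   sampling.
#' @return a `gps_estimand` with `point`, `mc_se` (`NA` when exact), `M`,
#'   `z_star`, `n_treated`.
#' @export
dad <- function(fit, z_star, M = 1000L, seed = NULL, exact = FALSE) {
  stopifnot(inherits(fit, "gps_drf"))
  treated <- fit$Z > z_star
  below <- fit$Z <= z_star
  if (!any(treated) || !any(below)) {
    stop("DAD undefined: need days on both sides of z* = ", z_star)
  }
  y_tr <- fit$y[treated]
  ad_at <- function(zv) {
    yhat <- predict_potential(fit, zv)
    sum(y_tr - yhat[treated])
  }
  support <- fit$Z[below]
  if (exact) {
    vals <- vapply(unique(support), ad_at, numeric(1L))
    wts <- as.numeric(table(factor(support, levels = unique(support))))
    wts <- wts / sum(wts)
    return(new_estimand("DAD", z_star = z_star,
                        point = sum(wts * vals), mc_se = NA_real_,
                        M = length(support), n_treated = sum(treated),
                        cause = fit$cause, exact = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  zm <- sample(support, M, replace = TRUE)
  # evaluate each distinct drawn value once
  uz <- unique(zm)
  vals <- vapply(uz, ad_at, numeric(1L))
  ad_m <- vals[match(zm, uz)]
  new_estimand("DAD", z_star = z_star, point = mean(ad_m),
               mc_se = stats::sd(ad_m) / sqrt(M), M = M,
               n_treated = sum(treated), cause = fit$cause, exact = FALSE)
}
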