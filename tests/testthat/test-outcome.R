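sim_outcome_inputs <- function(n = 300, seed = 17, K = 8) {
  set.seed(seed)
  z <- exp(rnorm(n, log(50), 0.5))
  R <- runif(n, 0.05, 1)
  zs <- (z - min(z)) / diff(range(z))
  eta <- 1 + 0.5 * zs
  y <- rpois(n, exp(eta))
  list(z = z, R = R, y = y, zs = zs, eta = eta, K = K)
}

test_that("an overwhelming penalty collapses onto the unpenalized GLM on [1, z, r]", {
  d <- sim_outcome_inputs()
  fit <- fit_outcome(d$y, d$z, d$R, K = d$K, lambda = 1e12)
  zs <- fit$basis$X[, 2]; rs <- fit$basis$X[, 3]
  ref <- glm(d$y ~ zs + rs, family = poisson())
  expect_equal(unname(fit$beta[1:3]), unname(coef(ref)), tolerance = 1e-6)
  expect_lt(max(abs(fit$beta[-(1:3)])), 1e-5)
})

test_that("unpenalized fit equals Poisson maximum likelihood on the full design", {
  d <- sim_outcome_inputs(n = 200, seed = 18, K = 5)
  fit <- fit_outcome(d$y, d$z, d$R, K = 5, lambda = 0)
  ref <- glm(d$y ~ fit$basis$X - 1, family = poisson())
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-6)
})

test_that("constant counts give a constant fitted mean", {
  d <- sim_outcome_inputs(n = 150, seed = 19, K = 5)
  y <- rep(7L, 150)
  fit <- fit_outcome(y, d$z, d$R, K = 5)
  expect_equal(fit$fitted, rep(7, 150), tolerance = 1e-6)
  expect_lt(fit$deviance, 1e-6)
})

test_that("a linear exposure signal is recovered", {
  d <- sim_outcome_inputs(n = 1000, seed = 20, K = 12)
  fit <- fit_outcome(d$y, d$z, d$R, K = 12)
  expect_lt(sqrt(mean((log(fit$fitted) - d$eta)^2)), 0.1)
  expect_gt(fit$beta[2], 0)
})

test_that("deviance is non-increasing in model flexibility", {
  d <- sim_outcome_inputs(n = 250, seed = 21, K = 8)
  lams <- c(0.01, 1, 100, 1e4)
  devs <- vapply(lams, function(l)
    fit_outcome(d$y, d$z, d$R, K = 8, lambda = l)$deviance, numeric(1))
  expect_true(all(diff(devs) >= -1e-6))
})

test_that("effective degrees of freedom stay within (3, 3 + K)", {
  d <- sim_outcome_inputs(n = 250, seed = 22, K = 8)
  fit <- fit_outcome(d$y, d$z, d$R, K = 8)
  expect_gt(fit$edf, 3 - 1e-8)
  expect_lt(fit$edf, 3 + 8 + 1e-8)
  expect_true(all(fit$fitted > 0))
})

test_that("selected smoothing beats every grid candidate on GCV", {
  d <- sim_outcome_inputs(n = 250, seed = 23, K = 8)
  grid <- 10^seq(-4, 4, length.out = 9)
  fit <- fit_outcome(d$y, d$z, d$R, K = 8, lambda_grid = grid)
  scores <- vapply(grid, function(l) {
    f <- fit_outcome(d$y, d$z, d$R, K = 8, lambda = l)
    gcv_score(f$deviance, length(d$y), f$edf)
  }, numeric(1))
  sel <- gcv_score(fit$deviance, length(d$y), fit$edf)
  expect_lte(sel, min(scores) + 1e-8)
})

test_that("fits are invariant to affine rescaling of the raw inputs", {
  d <- sim_outcome_inputs(n = 200, seed = 24, K = 6)
  f1 <- fit_outcome(d$y, d$z, d$R, K = 6, lambda = 5)
  f2 <- fit_outcome(d$y, 3 * d$z + 100, 0.2 * d$R + 0.05, K = 6, lambda = 5)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-8)
})

test_that("invalid outcome inputs are rejected", {
  d <- sim_outcome_inputs(n = 50, seed = 25, K = 5)
  expect_error(fit_outcome(d$y - 100L, d$z, d$R, K = 5), "non-negative")
  expect_error(fit_outcome(d$y + 0.5, d$z, d$R, K = 5), "integer")
  expect_error(fit_outcome(d$y, d$z, d$R - 2, K = 5), "positive")
})

test_that("the penalized fit agrees with an independent thin-plate GAM", {
  skip_if_not_installed("mgcv")
  sim <- simulate_pm_study(n_days = 500, seed = 26)
  idx <- which(!is.na(sim$series$pm10_lag01) & !is.na(sim$series$temp_lag03))
  z <- sim$series$pm10_lag01[idx]
  y <- sim$series$deaths_natural[idx]
  ef <- fit_exposure(sim$series)
  R <- actual_gps(ef)
  ours <- fit_outcome(y, z, R, K = 30)
  gam_fit <- mgcv::gam(y ~ s(z, R, bs = "tp", k = 33),
                       family = stats::quasipoisson())
  expect_gt(cor(ours$fitted, fitted(gam_fit)), 0.9)
  expect_lt(abs(ours$deviance - deviance(gam_fit)) / deviance(gam_fit), 0.2)
})
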