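test_that("the conditional aDRF with an always-true subset equals the unconditional one", {
  fit <- small_fit()
  zg <- seq(min(fit$Z), max(fit$Z), length.out = 12)
  a1 <- adrf(fit, z_grid = zg)
  a2 <- adrf(fit, z_grid = zg, subset = rep(TRUE, length(fit$y)))
  expect_identical(a1$point, a2$point)
  expect_error(adrf(fit, z_grid = numeric(0)), "non-empty")
  expect_error(adrf(fit, z_grid = zg, subset = rep(FALSE, length(fit$y))),
               "empty")
})

test_that("temperature strata partition the analysable days", {
  fit <- small_fit()
  st <- adrf_by_temperature(fit, z_grid = c(30, 60))
  expect_named(st, c("low", "medium", "high"))
  expect_equal(st$low$n_subset + st$medium$n_subset + st$high$n_subset,
               length(fit$y))
})

test_that("attributable deaths vanish above the maximum exposure and add over subsets", {
  fit <- small_fit()
  expect_warning(est <- attributable_deaths(fit, max(fit$Z) + 1), "AD is 0")
  expect_equal(est$point, 0)
  expect_equal(est$n_treated, 0L)

  est40 <- attributable_deaths(fit, 40)
  treated <- fit$Z > 40
  yhat <- predict_potential(fit, 40)
  parts <- (fit$y - yhat)[treated]
  half <- seq_len(floor(length(parts) / 2))
  expect_equal(est40$point, sum(parts[half]) + sum(parts[-half]))
  expect_equal(est40$n_treated, sum(treated))
})

test_that("DAD with a degenerate counterfactual distribution equals AD at that value", {
  fit <- small_fit()
  v <- 25
  deg <- fit
  deg$Z[deg$Z <= 40] <- v   # all below-threshold days share exposure v
  ex <- dad(deg, 40, exact = TRUE)
  mc <- dad(deg, 40, M = 200, seed = 2)
  treated <- deg$Z > 40
  manual <- sum(deg$y[treated] - predict_potential(deg, v)[treated])
  expect_equal(ex$point, manual, tolerance = 1e-10)
  expect_equal(mc$point, manual, tolerance = 1e-10)
})

test_that("DAD Monte Carlo is seeded and converges to the exact enumeration", {
  fit <- small_fit()
  expect_identical(dad(fit, 40, M = 300, seed = 3)$point,
                   dad(fit, 40, M = 300, seed = 3)$point)
  ex <- dad(fit, 40, exact = TRUE)$point
  mc <- dad(fit, 40, M = 5000, seed = 4)
  expect_lt(abs(mc$point - ex) / abs(ex), 0.05)
  expect_true(is.finite(mc$mc_se))
  expect_error(dad(fit, max(fit$Z) + 1), "both sides")
})

test_that("DAD dominates AD when the dose-response is non-decreasing", {
  fit <- small_fit()
  mono <- fit
  mono$outcome$beta[] <- 0
  mono$outcome$beta[1] <- log(mean(fit$y))
  mono$outcome$beta[2] <- 1.2       # increasing in z, flat in the GPS
  expect_gte(dad(mono, 40, exact = TRUE)$point,
             attributable_deaths(mono, 40)$point)
})

test_that("per-cause estimands are finite and independent across causes", {
  sim <- simulate_pm_study(n_days = 400, seed = 26)
  ads <- vapply(death_causes(), function(cc) {
    f <- gps_drf(sim$series, cause = cc, K = 12, lambda = 10)
    attributable_deaths(f, 40)$point
  }, numeric(1))
  expect_true(all(is.finite(ads)))
})

test_that("the bootstrap is deterministic given a seed and degenerate for constants", {
  fit <- small_fit()
  bt1 <- gps_boot(fit, function(f) 3.14, B = 60, seed = 5,
                  refit_lambda = "fixed")
  expect_equal(bt1$ci_low, 3.14)
  expect_equal(bt1$ci_high, 3.14)

  statf <- function(f) attributable_deaths(f, 40)$point
  b1 <- gps_boot(fit, statf, B = 60, seed = 6, refit_lambda = "fixed")
  b2 <- gps_boot(fit, statf, B = 60, seed = 6, refit_lambda = "fixed")
  expect_identical(b1$reps, b2$reps)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_lte(b1$ci_low, b1$ci_high)
  expect_error(gps_boot(fit, statf, B = 20), "at least 50")
})
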