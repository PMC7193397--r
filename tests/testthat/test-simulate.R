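test_that("the generator is reproducible and structurally valid", {
  s1 <- simulate_pm_study(n_days = 300, seed = 27)
  s2 <- simulate_pm_study(n_days = 300, seed = 27)
  expect_identical(as.data.frame(s1$series), as.data.frame(s2$series))
  expect_identical(s1$truth$alpha, s2$truth$alpha)

  df <- as.data.frame(s1$series)
  expect_true(all(diff(as.integer(df$date)) == 1))
  expect_true(all(df$humidity >= 20 & df$humidity <= 100))
  for (cc in c("deaths_natural", "deaths_cvd", "deaths_resp")) {
    expect_true(all(df[[cc]] >= 0 & df[[cc]] == round(df[[cc]])))
  }
  expect_true(all(df$pm10 > 0))
})

test_that("marginal exposure and count levels match the calibration targets", {
  stats <- t(vapply(1:6, function(s) {
    df <- as.data.frame(simulate_pm_study(seed = s)$series)
    c(mean(df$pm10), sd(df$pm10), mean(df$deaths_natural),
      mean(df$deaths_cvd), mean(df$deaths_resp))
  }, numeric(5)))
  m <- colMeans(stats)
  expect_gt(m[1], 47); expect_lt(m[1], 58)     # PM10 mean near 52.5
  expect_gt(m[2], 26); expect_lt(m[2], 40)     # PM10 sd near 33
  expect_equal(m[3], 28.0, tolerance = 0.05)
  expect_equal(m[4], 10.3, tolerance = 0.05)
  expect_equal(m[5], 2.5, tolerance = 0.06)
})

test_that("a zero dose-response slope gives a flat truth and zero impacts", {
  cfg <- pm_sim_config(gamma = c(natural = 0, cvd = 0, resp = 0))
  sim <- simulate_pm_study(n_days = 400, seed = 28, config = cfg)
  zg <- seq(10, 100, length.out = 7)
  mu <- true_adrf(sim$truth, zg)
  expect_equal(diff(range(mu)), 0)
  expect_equal(true_ad(sim$truth, 40), 0)
})

test_that("the true impact functions behave monotonically in threshold and slope", {
  sim <- simulate_pm_study(seed = 29)
  zs <- c(20, 30, 40, 50, 60)
  ads <- vapply(zs, function(z) true_ad(sim$truth, z), numeric(1))
  expect_true(all(diff(ads) <= 0))     # non-increasing in z*

  cfg2 <- pm_sim_config(gamma = c(natural = 0.36, cvd = 0.21, resp = 0.35))
  sim2 <- simulate_pm_study(seed = 29, config = cfg2)
  expect_gt(true_ad(sim2$truth, 40), true_ad(sim$truth, 40))
  expect_error(true_ad(sim$truth, max(sim$truth$Z) + 1), "z_star")
})

test_that("true DAD reduces to true AD when one day lies below the threshold", {
  sim <- simulate_pm_study(n_days = 365, seed = 30)
  zs <- sort(sim$truth$Z)
  z_star <- (zs[1] + zs[2]) / 2   # exactly one below-threshold day
  v <- zs[1]
  expect_equal(true_dad(sim$truth, z_star), true_ad(sim$truth, v),
               tolerance = 1e-10)
})

test_that("true conditional slopes order with a positive interaction", {
  cfg <- pm_sim_config(interaction = 0.1)
  sim <- simulate_pm_study(seed = 31, config = cfg)
  tr <- sim$truth
  zg <- c(30, 90)
  slope_for <- function(keep) {
    mu <- vapply(zg, function(z) {
      gz <- tr$gamma[["natural"]] * log(1 + z / tr$tau)
      mean((tr$lam0$natural * exp((1 + tr$interaction * tr$tdev) * gz))[keep])
    }, numeric(1))
    diff(mu) / diff(zg)
  }
  tl <- tr$tdev + 14.5
  expect_gt(slope_for(tl > 23), slope_for(tl <= 10))
})

test_that("the overdispersion option inflates the quasi-Poisson scale", {
  cfg <- pm_sim_config(overdispersion = 0.05)
  sim <- simulate_pm_study(n_days = 600, seed = 32, config = cfg)
  fit <- gps_drf(sim$series, cause = "natural", K = 12)
  expect_gt(fit$outcome$dispersion, 1.5)
})
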