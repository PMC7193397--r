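test_that("calendar spline has df per year columns and reproduces piecewise-linear trends", {
  days <- 1:1461
  B <- calendar_spline(days, df_per_year = 5, n_years = 4)
  expect_equal(ncol(B), 20)
  expect_equal(length(attr(B, "knots")), 19)

  # any continuous piecewise-linear function with breaks at the knots lies
  # in the span of [1, basis]
  kn <- c(1, attr(B, "knots"), 1461)
  set.seed(4)
  target_vals <- rnorm(length(kn))
  target <- approx(kn, target_vals, xout = days)$y
  fitted <- lm.fit(cbind(1, B), target)$fitted.values
  expect_lt(max(abs(fitted - target)), 1e-8)

  one <- calendar_spline(1:365, df_per_year = 1, n_years = 1)
  expect_equal(ncol(one), 1)
})

test_that("cubic quantile spline spans cubics and places knots at quantiles", {
  set.seed(5)
  x <- rnorm(400)
  B <- cubic_quantile_spline(x, df = 5)
  expect_equal(ncol(B), 5)
  expect_equal(attr(B, "knots"),
               unname(quantile(x, c(1, 2) / 3)), tolerance = 1e-12)
  # exact reproduction of a cubic polynomial
  target <- 1 - 2 * x + 0.5 * x^2 + 0.1 * x^3
  fitted <- lm.fit(cbind(1, B), target)$fitted.values
  expect_lt(max(abs(fitted - target)), 1e-8)

  B4 <- cubic_quantile_spline(x, df = 4)
  expect_equal(ncol(B4), 4)
  expect_equal(length(attr(B4, "knots")), 1)
  expect_error(cubic_quantile_spline(rep(1, 10)), "constant")
  expect_error(cubic_quantile_spline(x, df = 3), ">= 4")
})

test_that("thin-plate kernel and penalty have the stated structure", {
  # phi(d) = d^2 log d with phi(0) = phi(1) = 0
  expect_equal(gpsdrf:::tps_phi(c(0, 1, exp(1))), c(0, 0, exp(2)))

  set.seed(6)
  z <- runif(40); r <- runif(40)
  b <- radial_penalized_basis(z, r, K = 6)
  expect_equal(b$penalty, c(0, 0, 0, rep(1, 6)))
  expect_equal(dim(b$X), c(40, 9))
  expect_equal(unname(b$X[, 1]), rep(1, 40))
  # standardized inputs exactly in [0, 1]
  expect_true(all(b$X[, 2] >= 0 & b$X[, 2] <= 1))
  expect_error(radial_penalized_basis(z, r, K = 40), "distinct")
  expect_error(radial_penalized_basis(z, r, K = 3), "at least 4")
})

test_that("greedy max-min knot design is deterministic", {
  set.seed(7)
  z <- runif(100); r <- runif(100)
  b1 <- radial_penalized_basis(z, r, K = 10)
  b2 <- radial_penalized_basis(z, r, K = 10)
  expect_identical(b1$knots, b2$knots)
  expect_identical(b1$X, b2$X)
})

test_that("basis evaluation at the training points reproduces the design", {
  set.seed(8)
  z <- runif(60, 5, 200); r <- runif(60, 0.01, 1)
  b <- radial_penalized_basis(z, r, K = 8)
  Xnew <- eval_penalized_basis(b, z, r)
  expect_equal(unname(Xnew), unname(b$X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(Xnew, "n_clamped"), 0)
  # out-of-range points are clamped and counted
  Xout <- eval_penalized_basis(b, c(min(z) - 10, max(z) + 10), c(2, -1))
  expect_equal(attr(Xout, "n_clamped"), 2)
})

test_that("GCV score follows its closed form", {
  expect_equal(gcv_score(10, 100, 0), 0.1)
  expect_equal(gcv_score(20, 100, 0), 0.2)     # linear in deviance
  expect_equal(gcv_score(10, 100, 50), 100 * 10 / 50^2)
  expect_error(gcv_score(10, 100, 100), "edf")
})
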