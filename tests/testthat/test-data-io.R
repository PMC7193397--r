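test_that("lagged mean reproduces the lag 0-1 and lag 0-3 definitions", {
  expect_equal(lagged_mean(c(10, 30, 50, 70), 1), c(NA, 20, 40, 60))
  expect_equal(lagged_mean(c(0, 10, 20, 30), 3)[4], 15)
  v <- c(3, 1, 4, 1, 5)
  expect_identical(lagged_mean(v, 0), as.numeric(v))
  set.seed(1)
  x <- rnorm(50)
  expect_equal(lagged_mean(x, 1)[-1],
               (x[-1] + x[-length(x)]) / 2)
  expect_error(lagged_mean(1:3, 3), "smaller than the series length")
  expect_error(lagged_mean(1:3, -1), "non-negative")
})

test_that("lagging is translation-equivariant and prefix-stable", {
  set.seed(2)
  x <- rnorm(60)
  for (lag in c(1L, 3L)) {
    shifted <- lagged_mean(x + 7.5, lag)
    expect_equal(shifted, lagged_mean(x, lag) + 7.5)
    # dropping the first `lag` days leaves retained values unchanged
    kept <- lagged_mean(x, lag)[(2 * lag + 1):length(x)]
    redone <- lagged_mean(x[(lag + 1):length(x)], lag)[(lag + 1):(length(x) - lag)]
    expect_equal(kept, redone)
  }
})

test_that("study series computes lag variables and validates inputs", {
  df <- toy_daily_df(10, pm10 = seq(10, 100, by = 10))
  s <- study_series(df)
  expect_s3_class(s, "study_series")
  expect_equal(s$pm10_lag01[2:4], c(15, 25, 35))
  expect_true(all(is.na(s$pm10_lag01[1])))
  expect_equal(attr(s, "n_analysis"), 7)  # first 3 days lack temp lag 0-3

  expect_error(study_series(df[, setdiff(names(df), "humidity")]),
               "humidity")
  dup <- rbind(df, df[10, ])
  expect_error(study_series(dup), "duplicated")
  gap <- df; gap$date[10] <- gap$date[10] + 5
  expect_error(study_series(gap), "gapped")
  bad <- df; bad$deaths_cvd[3] <- -1
  expect_error(study_series(bad), "non-negative integer")
  badh <- df; badh$humidity[2] <- 140
  expect_error(study_series(badh), "humidity")
})

test_that("pre-lagged exposure columns are used as-is", {
  df <- toy_daily_df(10, pm10 = seq(10, 100, by = 10))
  s <- study_series(df, exposure_lagged = TRUE)
  expect_equal(s$pm10_lag01, df$pm10)
})

test_that("a synthetic series round-trips through write and read", {
  sim <- simulate_pm_study(n_days = 200, seed = 3)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_pm_series(sim$series, path)
  back <- read_pm_series(path, exposure_lagged = TRUE)
  for (col in c("pm10", "temp", "humidity", "pm10_lag01", "temp_lag03")) {
    expect_equal(back[[col]], sim$series[[col]], tolerance = 1e-12)
  }
  expect_identical(back$deaths_natural, sim$series$deaths_natural)
  expect_identical(back$date, sim$series$date)
})

test_that("column_map renames non-default CSV headers", {
  df <- toy_daily_df(8)
  names(df)[names(df) == "pm10"] <- "PM10_conc"
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  df$date <- format(df$date)
  write.csv(df, path, row.names = FALSE)
  s <- read_pm_series(path, column_map = c(pm10 = "PM10_conc"))
  expect_s3_class(s, "study_series")
  expect_error(read_pm_series(path, column_map = c(pm10 = "nope")),
               "absent column")
})
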