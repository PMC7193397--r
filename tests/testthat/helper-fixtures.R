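# small fixtures built in code; nothing is stored on disk

toy_daily_df <- function(n = 40, pm10 = NULL, start = "2003-01-01") {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  doy <- as.integer(format(dates, "%j"))
  set.seed(n + 1L)
  data.frame(
    date = dates,
    pm10 = if (is.null(pm10)) exp(rnorm(n, log(50), 0.3)) else pm10,
    temp = 15 - 8 * cos(2 * pi * doy / 365) + rnorm(n, 0, 2),
    humidity = pmin(pmax(70 + rnorm(n, 0, 8), 20), 100),
    holiday = as.integer(doy %in% c(1, 6)),
    influenza = as.integer(doy < 50),
    deaths_natural = rpois(n, 28),
    deaths_cvd = rpois(n, 10),
    deaths_resp = rpois(n, 2.5)
  )
}

# a small fitted model reused across method tests (cheap: fixed lambda)
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_pm_study(n_days = 400, seed = 11)
      cache <<- gps_drf(sim$series, cause = "natural", K = 15)
    }
    cache
  }
})
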