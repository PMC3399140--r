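# Synthetic winter weather generation and photoperiod.

test_that("daylight_hours matches solar geometry checkpoints", {
  # equinox: day ~ night everywhere (refraction adds a few minutes)
  expect_equal(daylight_hours(as.Date("2002-03-20"), 47.5), 12, tolerance = 0.025)
  # near-equatorial day length is ~12 h year-round
  expect_equal(daylight_hours(as.Date("2001-12-21"), 0.5), 12, tolerance = 0.02)
  expect_equal(daylight_hours(as.Date("2001-06-21"), 0.5), 12, tolerance = 0.02)
  # winter solstice at the Skagit mouth: independent NOAA-style solar
  # calculation gives ~8.2-8.4 h
  solstice <- daylight_hours(as.Date("2001-12-21"), 48.4)
  expect_gt(solstice, 8.2)
  expect_lt(solstice, 8.4)
})

test_that("daylight_hours is minimized at the winter solstice for preset latitudes", {
  dates <- winter_dates()
  for (sc in default_scenarios()[c("Skagit_1970s_A", "HammaHamma_1970s_A",
                                   "Nisqually_1970s_A")]) {
    h <- daylight_hours(dates, sc$latitude)
    min_date <- dates[which.min(h)]
    expect_lte(abs(as.numeric(min_date - as.Date("2001-12-21"))), 1)
    expect_true(all(h > 0 & h < 24))
  }
})

test_that("daylight_hours rejects polar and non-positive latitudes", {
  expect_error(daylight_hours(as.Date("2001-12-21"), 70), "latitude")
  expect_error(daylight_hours(as.Date("2001-12-21"), -10), "latitude")
})

test_that("generated winters satisfy the structural invariants", {
  sc <- climate_scenario(seed = 42)
  w <- generate_winter_weather(sc)
  expect_equal(nrow(w), 90)
  expect_identical(as.Date(w$date), winter_dates())
  expect_true(all(diff(as.Date(w$date)) == 1))
  expect_false(any(format(as.Date(w$date), "%m-%d") == "02-29"))
  expect_true(all(w$precip >= 0))
  expect_true(all(w$daylight > 0 & w$daylight < 24))
  expect_true(all(w$lw_day > 0 & w$lw_night > 0))
  expect_true(all(w$wind_day >= 0 & w$wind_night >= 0))
})

test_that("generation is seeded: reproducible, and distinct across seeds", {
  sc <- climate_scenario()
  w1 <- generate_winter_weather(sc, seed = 7)
  w2 <- generate_winter_weather(sc, seed = 7)
  w3 <- generate_winter_weather(sc, seed = 8)
  expect_identical(w1, w2)
  expect_false(isTRUE(all.equal(w1$t_day, w3$t_day)))
  expect_error(generate_winter_weather(sc), "seed")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); expected <- runif(3)
  set.seed(123); invisible(generate_winter_weather(climate_scenario(seed = 1)))
  expect_identical(runif(3), expected)
})

test_that("noise-free limit collapses to the configured mean", {
  sc <- climate_scenario(t_mean = 5, t_offset = c(0, 0, 0), anom_sd = 1e-12,
                         diurnal_range = 0, seed = 1)
  w <- generate_winter_weather(sc)
  expect_equal(w$t_day, rep(5, 90), tolerance = 1e-9)
  expect_equal(w$t_night, rep(5, 90), tolerance = 1e-9)
})

test_that("a uniform decade offset adds exactly under a shared seed", {
  base <- climate_scenario(t_mean = 4, t_offset = c(0, 0, 0), seed = 11)
  warm <- climate_scenario(t_mean = 4, t_offset = c(2, 2, 2), seed = 11)
  wb <- generate_winter_weather(base)
  ww <- generate_winter_weather(warm)
  expect_equal(ww$t_day - wb$t_day, rep(2, 90), tolerance = 1e-12)
  expect_equal(ww$t_night - wb$t_night, rep(2, 90), tolerance = 1e-12)
  # non-temperature drivers untouched by a temperature offset
  expect_identical(ww$precip, wb$precip)
  expect_identical(ww$wind_day, wb$wind_day)
})

test_that("day/night split conserves the daily mean under daylight weighting", {
  w <- generate_winter_weather(climate_scenario(diurnal_range = 3, seed = 5))
  mean_recovered <- daily_mean(w)
  # reconstruct the configured mean path from an identical zero-range run
  w0 <- generate_winter_weather(climate_scenario(diurnal_range = 0, seed = 5))
  expect_equal(mean_recovered, w0$t_day, tolerance = 1e-12)
})

test_that("replicate-winter temperature mean converges to mean + offsets", {
  sc <- climate_scenario(t_mean = 4, t_offset = c(1, 2.5, 2.5))
  nrep <- 1000
  winter_means <- vapply(seq_len(nrep), function(i) {
    mean(daily_mean(generate_winter_weather(sc, seed = i)))
  }, numeric(1))
  dates <- winter_dates()
  offset <- sc$t_offset[match(format(dates, "%m"), c("12", "01", "02"))]
  target <- mean(4 + offset)
  se <- stats::sd(winter_means) / sqrt(nrep)
  expect_lt(abs(mean(winter_means) - target), 3 * se)
})

test_that("longwave flux rises monotonically with configured temperature", {
  lw_at <- function(tm) {
    w <- generate_winter_weather(climate_scenario(t_mean = tm, seed = 3))
    c(w$lw_day, w$lw_night)
  }
  expect_true(all(lw_at(8) > lw_at(4)))
  expect_true(all(lw_at(4) > lw_at(0)))
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(climate_scenario(ar1 = 1), "ar1")
  expect_error(climate_scenario(ar1 = -0.1), "ar1")
  expect_error(climate_scenario(anom_sd = 0), "anom_sd")
  expect_error(climate_scenario(wet_prob = 1.2), "wet_prob")
  expect_error(climate_scenario(latitude = 80), "latitude")
})

test_that("default scenarios encode the site and decade structure", {
  sc <- default_scenarios()
  expect_length(sc, 12)
  winter_mean <- function(x) {
    dates <- winter_dates()
    off <- x$t_offset[match(format(dates, "%m"), c("12", "01", "02"))]
    mean(x$t_mean + off)
  }
  for (m in c("A", "B")) for (d in c("1970s", "2050s")) {
    nis <- sc[[paste0("Nisqually_", d, "_", m)]]
    ska <- sc[[paste0("Skagit_", d, "_", m)]]
    ham <- sc[[paste0("HammaHamma_", d, "_", m)]]
    # warmth ordering within each decade/model block
    expect_gt(winter_mean(nis), winter_mean(ska))
    expect_gt(winter_mean(ska), winter_mean(ham))
    # Nisqually has the driest parameters
    expect_lt(nis$wet_prob, min(ska$wet_prob, ham$wet_prob))
    expect_lt(nis$wet_prob * nis$precip_shape * nis$precip_scale,
              min(ska$wet_prob * ska$precip_shape * ska$precip_scale,
                  ham$wet_prob * ham$precip_shape * ham$precip_scale))
    for (x in list(nis, ska, ham)) {
      expect_gt(x$latitude, 47)
      expect_lt(x$latitude, 49)
    }
  }
  for (m in c("A", "B")) for (s in c("Skagit", "HammaHamma", "Nisqually")) {
    past <- sc[[paste0(s, "_1970s_", m)]]
    fut <- sc[[paste0(s, "_2050s_", m)]]
    expect_gt(winter_mean(fut), winter_mean(past))
    # warming concentrated in Jan-Feb
    expect_gt(fut$t_offset[2], fut$t_offset[1])
    expect_gt(fut$t_offset[3], fut$t_offset[1])
  }
})

test_that("generated 2050s winters are warmer than 1970s over many seeds", {
  sc <- default_scenarios()
  for (m in c("A", "B")) for (s in c("Skagit", "HammaHamma", "Nisqually")) {
    past <- sc[[paste0(s, "_1970s_", m)]]
    fut <- sc[[paste0(s, "_2050s_", m)]]
    mp <- mean(vapply(1:30, function(i) {
      mean(daily_mean(generate_winter_weather(past, seed = i)))
    }, numeric(1)))
    mf <- mean(vapply(1:30, function(i) {
      mean(daily_mean(generate_winter_weather(fut, seed = i)))
    }, numeric(1)))
    expect_gt(mf, mp)
  }
})

test_that("weather CSV round-trips and rejects malformed input", {
  w <- generate_winter_weather(climate_scenario(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  back <- read_weather_csv(path)
  for (col in setdiff(names(w), "date")) {
    expect_equal(back[[col]], w[[col]], tolerance = 1e-12, label = col)
  }
  expect_identical(as.Date(back$date), as.Date(w$date))

  df <- w; class(df) <- "data.frame"
  names(df) <- c("date", "t_day_C", "t_night_C", "wind_day_ms", "wind_night_ms",
                 "precip_mm", "lw_day_Wm2", "lw_night_Wm2", "daylight_h")
  bad_path <- withr::local_tempfile(fileext = ".csv")

  # negative precipitation names the offending row
  bad <- df; bad$precip_mm[17] <- -1
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_weather_csv(bad_path), "precipitation.*17")

  # date gap
  utils::write.csv(df[-10, ], bad_path, row.names = FALSE)
  expect_error(read_weather_csv(bad_path), "gap")

  # missing column
  utils::write.csv(df[, -6], bad_path, row.names = FALSE)
  expect_error(read_weather_csv(bad_path), "missing columns.*precip_mm")

  # empty file
  utils::write.csv(df[0, ], bad_path, row.names = FALSE)
  expect_error(read_weather_csv(bad_path), "no records")
})
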