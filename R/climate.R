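# Synthetic winter weather generation: seeded daily series (Dec 1 - Feb 28)
# emulating downscaled regional-climate output for Puget Sound river mouths.

STEFAN_BOLTZMANN <- 5.670374419e-8 # W m^-2 K^-4

#' Winter season date sequence
#'
#' The 90-day winter season, December 1 through February 28. A fixed
#' non-leap reference winter is used so that trajectories from different
#' scenarios align day-for-day; February 29 is never emitted.
#'
#' @return A `Date` vector of length 90.
#' @export
winter_dates <- function() {
  seq(as.Date("2001-12-01"), as.Date("2002-02-28"), by = "day")
}

#' Astronomical day length
#'
#' Photoperiod (hours between sunrise and sunset) from solar declination and
#' the sunset hour angle, using the conventional solar zenith of 90.833
#' degrees (atmospheric refraction plus the solar disk radius).
#'
#' @param date Date (or coercible) — vectorized.
#' @param latitude Latitude in degrees north, in (0, 66). Polar latitudes,
#'   where the sun may not rise or set, are rejected.
#' @return Day length in hours, in (0, 24).
#' @export
daylight_hours <- function(date, latitude) {
  stopifnot(length(latitude) == 1L, is.finite(latitude))
  if (latitude <= 0 || latitude >= 66) {
    stop("latitude must lie in (0, 66) degrees north; polar day/night not supported")
  }
  date <- as.Date(date)
  yday <- as.integer(format(date, "%j"))
  decl <- 23.45 * sin(2 * pi * (284 + yday) / 365) * pi / 180
  lat <- latitude * pi / 180
  zenith <- 90.833 * pi / 180
  cos_h <- (cos(zenith) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  cos_h <- pmin(1, pmax(-1, cos_h))
  24 * acos(cos_h) / pi
}

#' Construct a climate scenario
#'
#' Bundles the parameters of the synthetic winter weather generator for one
#' site x decade x model-analog cell. Temperature is modelled as a site mean
#' plus month-specific decade warming offsets plus AR(1) anomalies;
#' precipitation as Bernoulli wet-day occurrence times a gamma amount; wind
#' as Weibull draws; downward longwave radiation as effective emissivity
#' times sigma*T^4 with cloud-driven emissivity, cloud cover correlated with
#' precipitation occurrence.
#'
#' @param site,decade,model Labels for the grid cell (free-form strings).
#' @param latitude Degrees north, in (0, 66); drives photoperiod only.
#' @param t_mean Site winter mean air temperature, degrees C.
#' @param t_offset Decade warming offsets, degrees C, a length-3 numeric
#'   named or ordered (Dec, Jan, Feb).
#' @param ar1 AR(1) coefficient of daily temperature anomalies, in \[0, 1).
#' @param anom_sd Stationary (marginal) standard deviation of the
#'   temperature anomalies, degrees C, > 0.
#' @param diurnal_range Day/night temperature split amplitude, degrees C.
#'   `t_day = t_mean + diurnal_range * (1 - daylight/24)` and `t_night`
#'   correspondingly lower, so the daylight-weighted daily mean is conserved.
#' @param wet_prob Probability a day is wet, in \[0, 1\].
#' @param precip_shape,precip_scale Gamma shape and scale (mm) of wet-day
#'   precipitation amounts.
#' @param wind_shape,wind_scale Weibull shape and scale (m s^-1) of wind.
#' @param eps_clear Clear-sky effective emissivity.
#' @param eps_cloud Emissivity increment at full cloud cover.
#' @param cloud_mean,cloud_sd Mean and SD of daily cloud fraction before
#'   conditioning on precipitation occurrence.
#' @param cloud_wet_shift Cloud-fraction shift applied on wet (+) and dry
#'   (-) days before clamping to \[0, 1\].
#' @param seed Integer seed for [generate_winter_weather()]; may be `NULL`
#'   here and supplied at generation time.
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(site = "custom", decade = "custom", model = "custom",
                             latitude = 47.5,
                             t_mean = 4, t_offset = c(0, 0, 0),
                             ar1 = 0.7, anom_sd = 3, diurnal_range = 2,
                             wet_prob = 0.6, precip_shape = 0.8, precip_scale = 8,
                             wind_shape = 2, wind_scale = 4,
                             eps_clear = 0.70, eps_cloud = 0.20,
                             cloud_mean = 0.75, cloud_sd = 0.15,
                             cloud_wet_shift = 0.15,
                             seed = NULL) {
  stopifnot(length(t_offset) == 3L, is.numeric(t_offset))
  if (!(ar1 >= 0 && ar1 < 1)) stop("ar1 must lie in [0, 1)")
  if (!(anom_sd > 0)) stop("anom_sd must be > 0")
  if (!(wet_prob >= 0 && wet_prob <= 1)) stop("wet_prob must lie in [0, 1]")
  if (!(latitude > 0 && latitude < 66)) stop("latitude must lie in (0, 66)")
  if (!(precip_shape > 0 && precip_scale > 0)) stop("gamma precipitation parameters must be > 0")
  if (!(wind_shape > 0 && wind_scale > 0)) stop("Weibull wind parameters must be > 0")
  if (!(eps_clear > 0 && eps_clear + eps_cloud <= 1)) {
    stop("emissivities must satisfy 0 < eps_clear and eps_clear + eps_cloud <= 1")
  }
  structure(list(
    site = site, decade = decade, model = model, latitude = latitude,
    t_mean = t_mean, t_offset = unname(t_offset),
    ar1 = ar1, anom_sd = anom_sd, diurnal_range = diurnal_range,
    wet_prob = wet_prob, precip_shape = precip_shape, precip_scale = precip_scale,
    wind_shape = wind_shape, wind_scale = wind_scale,
    eps_clear = eps_clear, eps_cloud = eps_cloud,
    cloud_mean = cloud_mean, cloud_sd = cloud_sd,
    cloud_wet_shift = cloud_wet_shift,
    seed = seed
  ), class = "climate_scenario")
}

#' @export
print.climate_scenario <- function(x, ...) {
  cat(sprintf("<climate_scenario> %s / %s / model %s (lat %.2fN)\n",
              x$site, x$decade, x$model, x$latitude))
  cat(sprintf("  T mean %.2f C, offsets (Dec,Jan,Feb) = %s, AR1 %.2f, anom SD %.2f\n",
              x$t_mean, paste(sprintf("%+.1f", x$t_offset), collapse = "/"),
              x$ar1, x$anom_sd))
  invisible(x)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate one synthetic winter of daily weather
#'
#' Draws a 90-day (Dec 1 - Feb 28) daily weather series from a
#' [climate_scenario()]. Identical scenario and seed give bit-identical
#' output. A fixed number of random variates is consumed per winter
#' regardless of parameter values, so two scenarios differing only in a
#' deterministic parameter (for example a decade warming offset) share the
#' same anomalies under the same seed.
#'
#' @param scenario A `climate_scenario`.
#' @param seed Integer seed; defaults to `scenario$seed`.
#' @return A `weather_series`: a data.frame with one row per day and columns
#'   `date`, `t_day`, `t_night` (deg C), `wind_day`, `wind_night` (m s^-1),
#'   `precip` (mm day^-1), `lw_day`, `lw_night` (W m^-2), `daylight` (h).
#' @export
generate_winter_weather <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "climate_scenario"))
  if (is.null(seed)) stop("a seed is required (in the scenario or as an argument)")
  dates <- winter_dates()
  n <- length(dates)
  month <- format(dates, "%m")
  offset <- scenario$t_offset[match(month, c("12", "01", "02"))]

  draws <- with_seed(seed, {
    innov_sd <- scenario$anom_sd * sqrt(1 - scenario$ar1^2)
    anom <- numeric(n)
    anom[1] <- stats::rnorm(1, 0, scenario$anom_sd)
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (j in 2:n) anom[j] <- scenario$ar1 * anom[j - 1] + eps[j - 1]
    list(
      anom = anom,
      wet = stats::runif(n) < scenario$wet_prob,
      amount = stats::rgamma(n, shape = scenario$precip_shape,
                             scale = scenario$precip_scale),
      wind_day = stats::rweibull(n, scenario$wind_shape, scenario$wind_scale),
      wind_night = stats::rweibull(n, scenario$wind_shape, scenario$wind_scale),
      cloud = stats::rnorm(n, scenario$cloud_mean, scenario$cloud_sd)
    )
  })

  t_mean <- scenario$t_mean + offset + draws$anom
  daylight <- daylight_hours(dates, scenario$latitude)
  dfrac <- daylight / 24
  t_day <- t_mean + scenario$diurnal_range * (1 - dfrac)
  t_night <- t_mean - scenario$diurnal_range * dfrac

  precip <- ifelse(draws$wet, draws$amount, 0)
  cloud <- pmin(1, pmax(0, draws$cloud +
                          ifelse(draws$wet, scenario$cloud_wet_shift,
                                 -scenario$cloud_wet_shift)))
  eps_eff <- scenario$eps_clear + scenario$eps_cloud * cloud
  lw_day <- eps_eff * STEFAN_BOLTZMANN * (t_day + 273.15)^4
  lw_night <- eps_eff * STEFAN_BOLTZMANN * (t_night + 273.15)^4

  out <- data.frame(
    date = dates, t_day = t_day, t_night = t_night,
    wind_day = draws$wind_day, wind_night = draws$wind_night,
    precip = precip, lw_day = lw_day, lw_night = lw_night,
    daylight = daylight
  )
  class(out) <- c("weather_series", "data.frame")
  validate_weather(out)
  out
}

#' Daylight-weighted daily mean of a day/night-partitioned variable
#'
#' @param weather A `weather_series`.
#' @param day,night Column names of the day and night components.
#' @return Numeric vector of daily means weighted by hours of light/dark.
#' @export
daily_mean <- function(weather, day = "t_day", night = "t_night") {
  h <- weather$daylight
  (h * weather[[day]] + (24 - h) * weather[[night]]) / 24
}

validate_weather <- function(weather, file = NULL) {
  where <- if (is.null(file)) "weather series" else file
  required <- c("date", "t_day", "t_night", "wind_day", "wind_night",
                "precip", "lw_day", "lw_night", "daylight")
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(weather) == 0L) stop(sprintf("%s: no records", where))
  num <- required[-1]
  for (col in num) {
    bad <- which(!is.finite(weather[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric or missing %s in row(s) %s", where, col,
                   paste(utils::head(bad, 5), collapse = ", ")))
    }
  }
  bad <- which(weather$precip < 0)
  if (length(bad)) {
    stop(sprintf("%s: negative precipitation in row(s) %s", where,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(weather$daylight <= 0 | weather$daylight >= 24)
  if (length(bad)) {
    stop(sprintf("%s: daylight outside (0, 24) in row(s) %s", where,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(weather$lw_day <= 0 | weather$lw_night <= 0)
  if (length(bad)) {
    stop(sprintf("%s: non-positive longwave flux in row(s) %s", where,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  d <- as.Date(weather$date)
  if (any(diff(d) != 1)) {
    gaps <- which(diff(d) != 1)
    stop(sprintf("%s: date gaps after row(s) %s", where,
                 paste(utils::head(gaps, 5), collapse = ", ")))
  }
  invisible(weather)
}

# Column mapping between internal names and the on-disk CSV schema.
weather_csv_schema <- c(
  date = "date", t_day = "t_day_C", t_night = "t_night_C",
  wind_day = "wind_day_ms", wind_night = "wind_night_ms",
  precip = "precip_mm", lw_day = "lw_day_Wm2", lw_night = "lw_night_Wm2",
  daylight = "daylight_h"
)

#' Read and write winter weather CSV files
#'
#' The on-disk schema is
#' `date,t_day_C,t_night_C,wind_day_ms,wind_night_ms,precip_mm,lw_day_Wm2,lw_night_Wm2,daylight_h`
#' with ISO-8601 dates. `read_weather_csv(write_weather_csv(x, p))` is the
#' identity on valid series; malformed files are rejected with the
#' offending rows named.
#'
#' @param path File path.
#' @param weather A `weather_series`.
#' @return `read_weather_csv` returns a `weather_series`;
#'   `write_weather_csv` returns `path` invisibly.
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop(sprintf("%s: no records", path))
  missing_cols <- setdiff(unname(weather_csv_schema), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing columns: %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw[, unname(weather_csv_schema)]
  names(out) <- names(weather_csv_schema)
  for (col in names(weather_csv_schema)[-1]) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out$date <- as.Date(out$date)
  if (anyNA(out$date)) {
    stop(sprintf("%s: unparseable date in row(s) %s", path,
                 paste(utils::head(which(is.na(out$date)), 5), collapse = ", ")))
  }
  class(out) <- c("weather_series", "data.frame")
  validate_weather(out, file = path)
  out
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  validate_weather(weather)
  out <- weather[, names(weather_csv_schema)]
  names(out) <- unname(weather_csv_schema)
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Preset site x decade x model-analog climate scenarios
#'
#' Twelve presets: three Puget Sound river-mouth sites (Skagit, Hamma Hamma,
#' Nisqually), two decades (1970s, 2050s) and two regional climate model
#' analogs ("A": warmer and wetter-biased analog; "B": colder and drier
#' analog). Within each decade Nisqually is warmest and Hamma Hamma coldest;
#' Nisqually carries the lowest precipitation parameters; each 2050s preset
#' is warmer than its 1970s counterpart with larger warming in January and
#' February than December, and slightly lower cloud cover. Magnitudes are
#' calibrated choices of this package, not published values (the source
#' climate fields are not redistributed); they are documented in the
#' methods vignette.
#'
#' @return Named list of 12 [climate_scenario()] objects; names are
#'   `"<site>_<decade>_<model>"`. Seeds are unset — the scenario pipeline
#'   assigns per-cell seeds.
#' @export
default_scenarios <- function() {
  sites <- list(
    Skagit     = list(latitude = 48.40, t_mean = 3.6, wet_prob = 0.65, precip_scale = 8),
    HammaHamma = list(latitude = 47.55, t_mean = 3.0, wet_prob = 0.70, precip_scale = 10),
    Nisqually  = list(latitude = 47.10, t_mean = 4.4, wet_prob = 0.50, precip_scale = 5)
  )
  models <- list(
    A = list(t_shift = 0,    precip_mult = 1),
    B = list(t_shift = -0.8, precip_mult = 0.85)
  )
  decades <- list(
    `1970s` = list(t_offset = c(0, 0, 0), cloud_mean = 0.75),
    `2050s` = list(t_offset = c(1.0, 2.5, 2.5), cloud_mean = 0.70)
  )
  out <- list()
  for (s in names(sites)) for (d in names(decades)) for (m in names(models)) {
    sc <- climate_scenario(
      site = s, decade = d, model = m,
      latitude = sites[[s]]$latitude,
      t_mean = sites[[s]]$t_mean + models[[m]]$t_shift,
      t_offset = decades[[d]]$t_offset,
      wet_prob = sites[[s]]$wet_prob,
      precip_scale = sites[[s]]$precip_scale * models[[m]]$precip_mult,
      cloud_mean = decades[[d]]$cloud_mean
    )
    out[[paste(s, d, m, sep = "_")]] <- sc
  }
  out
}
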