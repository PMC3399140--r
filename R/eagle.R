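# Daily food-consumption bioenergetics of an overwintering bald eagle.
#
# Energy expenditure is an activity-budget-weighted sum of metabolic heat
# production in five states (gravel-bar feeding/waiting, daytime perching,
# nighttime roosting, flapping flight, gliding flight), each evaluated with
# that phase's day or night weather. The bird eats enough carcass each day
# to stay at constant mass, so consumption = expenditure / diet energy
# density.

#' Construct an eagle bioenergetics model
#'
#' All constants are configuration. The defaults describe a 4.5-kg adult
#' feeding on chum salmon carcasses.
#'
#' @param mass Body mass, kg.
#' @param wme Diet metabolizable energy density, kJ per gram wet mass.
#'   (Printed diet energy densities for salmon carcass are of order
#'   3.8 kJ/g wet; a per-kilogram reading would be dimensionally
#'   inconsistent with gram-scale daily intakes.)
#' @param bmr_coeff,bmr_exponent Allometric basal metabolism,
#'   `BMR_total = bmr_coeff * mass^bmr_exponent` kJ day^-1; defaults are a
#'   standard non-passerine allometry. [bmr()] reports the mass-specific
#'   rate.
#' @param t_lc Lower critical temperature, degrees C: below it resting
#'   metabolism rises linearly.
#' @param cold_slope Thermoregulatory cost, kJ kg^-1 day^-1 per degree C
#'   below `t_lc`.
#' @param wind_coeff Convective surcharge, kJ kg^-1 day^-1 per m s^-1.
#' @param precip_coeff Wetting surcharge, kJ kg^-1 day^-1 per mm day^-1.
#' @param rad_coeff Radiative surcharge, kJ kg^-1 day^-1 per W m^-2 of
#'   downward-longwave deficit relative to [reference_longwave()].
#' @param ref_emissivity Effective sky emissivity defining the neutral
#'   longwave flux at a given air temperature.
#' @param active_mult,passive_mult Flapping and gliding flight cost as
#'   multiples of BMR.
#' @param activity_mult Active (gravel-bar) standard metabolism as a
#'   multiple of resting standard metabolism.
#' @return An `eagle_model`.
#' @export
eagle_model <- function(mass = 4.5, wme = 3.764,
                        bmr_coeff = 327.6, bmr_exponent = 0.723,
                        t_lc = 10, cold_slope = 6,
                        wind_coeff = 5, precip_coeff = 1.5,
                        rad_coeff = 0.3, ref_emissivity = 0.85,
                        active_mult = 12.5, passive_mult = 3.5,
                        activity_mult = 2) {
  if (!(mass > 0)) stop("mass must be > 0")
  if (!(wme > 0)) stop("wme must be > 0")
  if (!(active_mult > passive_mult && passive_mult > 1)) {
    stop("flight multipliers must satisfy active_mult > passive_mult > 1")
  }
  if (any(c(cold_slope, wind_coeff, precip_coeff, rad_coeff) < 0)) {
    stop("stress-cost coefficients must be >= 0")
  }
  structure(list(mass = mass, wme = wme,
                 bmr_coeff = bmr_coeff, bmr_exponent = bmr_exponent,
                 t_lc = t_lc, cold_slope = cold_slope,
                 wind_coeff = wind_coeff, precip_coeff = precip_coeff,
                 rad_coeff = rad_coeff, ref_emissivity = ref_emissivity,
                 active_mult = active_mult, passive_mult = passive_mult,
                 activity_mult = activity_mult),
            class = "eagle_model")
}

#' @export
print.eagle_model <- function(x, ...) {
  cat(sprintf("<eagle_model> %.1f kg, WME %.3f kJ/g, BMR %.1f kJ/kg/day, t_lc %.1f C\n",
              x$mass, x$wme, bmr(x), x$t_lc))
  invisible(x)
}

#' Mass-specific basal metabolic rate
#'
#' `bmr_coeff * mass^bmr_exponent / mass`, kJ kg^-1 day^-1.
#'
#' @param model An `eagle_model`.
#' @export
bmr <- function(model) {
  stopifnot(inherits(model, "eagle_model"))
  model$bmr_coeff * model$mass^model$bmr_exponent / model$mass
}

#' Standard metabolic rate at a temperature
#'
#' Resting: BMR within the thermoneutral zone (T >= t_lc), rising linearly
#' below it. Active: the resting value times `activity_mult`. Continuous at
#' `t_lc`.
#'
#' @param model An `eagle_model`.
#' @param temperature Air temperature, degrees C (vectorized).
#' @param state `"rest"` or `"active"`.
#' @return kJ kg^-1 day^-1.
#' @export
smr <- function(model, temperature, state = c("rest", "active")) {
  state <- match.arg(state)
  rest <- bmr(model) + model$cold_slope * pmax(0, model$t_lc - temperature)
  if (state == "active") model$activity_mult * rest else rest
}

#' Neutral downward longwave flux at an air temperature
#'
#' `ref_emissivity * sigma * T_K^4`: the sky flux at which the radiative
#' surcharge of [metabolic_heat()] vanishes.
#'
#' @inheritParams smr
#' @return W m^-2.
#' @export
reference_longwave <- function(model, temperature) {
  model$ref_emissivity * STEFAN_BOLTZMANN * (temperature + 273.15)^4
}

#' Metabolic heat production under weather forcing
#'
#' Standard metabolic rate plus nonnegative surcharges for wind,
#' precipitation, and downward-longwave deficit:
#' `M = SMR(T, state) + wind_coeff*wind + precip_coeff*precip +
#' rad_coeff * max(0, reference_longwave(T) - lw)`.
#' Non-increasing in longwave flux and, below `t_lc` (where the cold slope
#' dominates the reference-flux drift), in temperature; non-decreasing in
#' wind and precipitation.
#'
#' @inheritParams smr
#' @param wind Wind speed, m s^-1 (>= 0).
#' @param precip Precipitation, mm day^-1 (>= 0).
#' @param lw Downward longwave flux, W m^-2 (> 0).
#' @return kJ kg^-1 day^-1.
#' @export
metabolic_heat <- function(model, temperature, wind, precip, lw,
                           state = c("rest", "active")) {
  if (any(wind < 0)) stop("wind must be >= 0")
  if (any(precip < 0)) stop("precip must be >= 0")
  if (any(lw <= 0)) stop("longwave flux must be > 0")
  smr(model, temperature, state) +
    model$wind_coeff * wind +
    model$precip_coeff * precip +
    model$rad_coeff * pmax(0, reference_longwave(model, temperature) - lw)
}

#' Construct an activity budget
#'
#' Fractions of the 24-h day in each state: gravel-bar feeding/waiting
#' (`f_gb`), daytime perching (`f_p`), nighttime roosting (`f_r`), active
#' flapping flight (`f_af`), passive gliding flight (`f_pf`). Must be
#' nonnegative and sum to 1.
#'
#' @param f_gb,f_p,f_r,f_af,f_pf Fractions of 24 h.
#' @return An `activity_budget`.
#' @export
activity_budget <- function(f_gb, f_p, f_r, f_af, f_pf) {
  f <- c(f_gb = f_gb, f_p = f_p, f_r = f_r, f_af = f_af, f_pf = f_pf)
  if (any(f < 0)) stop("activity fractions must be >= 0")
  if (abs(sum(f) - 1) > 1e-8) {
    stop(sprintf("activity fractions must sum to 1 (got %.6f)", sum(f)))
  }
  structure(as.list(f), class = "activity_budget")
}

#' Derive the daily activity budget from photoperiod
#'
#' All dark hours are spent roosting (`f_r = 1 - daylight/24`); daylight is
#' divided among gravel-bar feeding/waiting, perching, and the two flight
#' modes in fixed proportions.
#'
#' @param daylight Photoperiod, hours.
#' @param gb,perch,af,pf Daylight shares (must sum to 1).
#' @return An `activity_budget`.
#' @export
budget_from_daylight <- function(daylight, gb = 0.35, perch = 0.55,
                                 af = 0.04, pf = 0.06) {
  if (abs(gb + perch + af + pf - 1) > 1e-8) stop("daylight shares must sum to 1")
  d <- daylight / 24
  activity_budget(f_gb = gb * d, f_p = perch * d, f_r = 1 - d,
                  f_af = af * d, f_pf = pf * d)
}

#' Daily food consumption of one eagle
#'
#' Mass-specific daily energy expenditure is the activity-weighted sum
#' `f_gb*M_day(active) + f_p*M_day(rest) + f_r*M_night(rest) +
#' f_af*active_mult*BMR + f_pf*passive_mult*BMR`, with each `M` evaluated
#' at that phase's day or night temperature, wind, and longwave flux (the
#' daily precipitation total applies to both phases). Consumption in grams
#' is expenditure times body mass divided by the diet energy density
#' (constant-mass balance).
#'
#' @param model An `eagle_model`.
#' @param day One weather day: a single-row `weather_series` or a list with
#'   fields `t_day`, `t_night`, `wind_day`, `wind_night`, `precip`,
#'   `lw_day`, `lw_night`, `daylight`.
#' @param budget An `activity_budget`; defaults to
#'   [budget_from_daylight()] at the day's photoperiod.
#' @return A `daily_consumption` list: `c_grams` (g bird^-1 day^-1),
#'   `c_energy` (kJ bird^-1 day^-1), `wmi` (g kg^-1 day^-1), and the
#'   per-activity energy breakdown `components` (kJ bird^-1 day^-1,
#'   summing to `c_energy`).
#' @export
daily_consumption <- function(model, day, budget = NULL) {
  stopifnot(inherits(model, "eagle_model"))
  if (is.data.frame(day)) {
    stopifnot(nrow(day) == 1L)
    day <- as.list(day)
  }
  if (is.null(budget)) budget <- budget_from_daylight(day$daylight)
  if (!inherits(budget, "activity_budget")) {
    stop("budget must be an activity_budget")
  }
  b <- bmr(model)
  m_gb <- metabolic_heat(model, day$t_day, day$wind_day, day$precip,
                         day$lw_day, state = "active")
  m_p <- metabolic_heat(model, day$t_day, day$wind_day, day$precip,
                        day$lw_day, state = "rest")
  m_r <- metabolic_heat(model, day$t_night, day$wind_night, day$precip,
                        day$lw_night, state = "rest")
  per_kg <- c(
    gb_kJ = budget$f_gb * m_gb,
    perch_kJ = budget$f_p * m_p,
    roost_kJ = budget$f_r * m_r,
    af_kJ = budget$f_af * model$active_mult * b,
    pf_kJ = budget$f_pf * model$passive_mult * b
  )
  components <- per_kg * model$mass
  c_energy <- sum(components)
  c_grams <- c_energy / model$wme
  structure(list(
    c_grams = c_grams,
    c_energy = c_energy,
    wmi = c_grams / model$mass,
    components = components
  ), class = "daily_consumption")
}

#' Season total food consumption
#'
#' Sums [daily_consumption()] over a full winter weather series, with the
#' activity budget recomputed each day from that day's photoperiod (all
#' dark hours roosting).
#'
#' @param model An `eagle_model`.
#' @param weather A full-season `weather_series`.
#' @param edible_mass_g Edible wet mass per carcass, grams, used for the
#'   carcass-equivalents conversion.
#' @param ... Daylight shares passed to [budget_from_daylight()].
#' @return A `season_consumption` list: `total_kJ`, `total_g`,
#'   `carcass_equivalents`, and `daily`, a data.frame with columns `date`,
#'   `c_grams`, `c_kJ`, `wmi` and the per-activity kJ breakdown.
#' @export
season_consumption <- function(model, weather, edible_mass_g = 3652, ...) {
  validate_weather(weather)
  n <- nrow(weather)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    d <- as.list(weather[j, ])
    dc <- daily_consumption(model, d, budget_from_daylight(d$daylight, ...))
    rows[[j]] <- c(c_grams = dc$c_grams, c_kJ = dc$c_energy, wmi = dc$wmi,
                   dc$components)
  }
  daily <- cbind(data.frame(date = weather$date),
                 as.data.frame(do.call(rbind, rows)))
  structure(list(
    total_kJ = sum(daily$c_kJ),
    total_g = sum(daily$c_grams),
    carcass_equivalents = sum(daily$c_grams) / edible_mass_g,
    daily = daily
  ), class = "season_consumption")
}

#' @export
print.season_consumption <- function(x, ...) {
  cat(sprintf("<season_consumption> %.0f kJ, %.0f g (%.1f carcass-equivalents) over %d days\n",
              x$total_kJ, x$total_g, x$carcass_equivalents, nrow(x$daily)))
  invisible(x)
}
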