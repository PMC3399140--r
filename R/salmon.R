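# Hypothetical chum salmon run: normally distributed stream entry over a
# 10-week window starting Dec 1, a fixed lifespan on the spawning grounds,
# then cohort-wise temperature-driven decay of the carcass pool, summed
# daily until Feb 28.

#' Configure the hypothetical chum salmon run
#'
#' Defaults describe a run of 40,560 adults entering from December 1 over
#' 10 weeks with normally distributed entry timing, 10 days on the spawning
#' grounds, 3.652 kg wet mass per fish of which 16% is dry matter.
#'
#' @param n_fish Total run size (> 0).
#' @param run_duration Length of the entry window, days.
#' @param entry_mean Mean entry day as an offset from December 1, days.
#' @param entry_sd SD of entry timing, days; default spans the window at
#'   +/- 3 SD.
#' @param lifespan Days alive on the spawning grounds before entering the
#'   carcass pool (>= 0).
#' @param wet_mass Wet mass per fish, kg.
#' @param dry_fraction Dry-matter fraction of wet mass, in (0, 1].
#' @return A `salmon_run_config`.
#' @export
salmon_run_config <- function(n_fish = 40560, run_duration = 70,
                              entry_mean = 35, entry_sd = 70 / 6,
                              lifespan = 10, wet_mass = 3.652,
                              dry_fraction = 0.16) {
  if (!(n_fish >= 0)) stop("n_fish must be >= 0")
  if (!(run_duration > 0)) stop("run_duration must be > 0")
  if (!(entry_sd > 0)) stop("entry_sd must be > 0")
  if (!(lifespan >= 0)) stop("lifespan must be >= 0")
  if (!(wet_mass > 0)) stop("wet_mass must be > 0")
  if (!(dry_fraction > 0 && dry_fraction <= 1)) stop("dry_fraction must lie in (0, 1]")
  n_days <- length(winter_dates())
  if (run_duration + lifespan > n_days) {
    stop("run_duration + lifespan exceeds the 90-day season: some fish would die after Feb 28")
  }
  structure(list(n_fish = n_fish, run_duration = run_duration,
                 entry_mean = entry_mean, entry_sd = entry_sd,
                 lifespan = lifespan, wet_mass = wet_mass,
                 dry_fraction = dry_fraction),
            class = "salmon_run_config")
}

#' Daily stream-entry counts
#'
#' Truncated-normal entry mass over the run window `[0, run_duration)`
#' (offsets from Dec 1), discretized to whole fish by largest-remainder
#' apportionment so the counts sum exactly to `n_fish`.
#'
#' @param config A [salmon_run_config()].
#' @return Integer vector of length 90 (one element per season day,
#'   Dec 1 = day 1); zero outside the entry window.
#' @export
entry_schedule <- function(config) {
  stopifnot(inherits(config, "salmon_run_config"))
  n_days <- length(winter_dates())
  entries <- integer(n_days)
  if (config$n_fish == 0) return(entries)
  edges <- 0:config$run_duration
  p <- diff(stats::pnorm(edges, config$entry_mean, config$entry_sd))
  p <- p / sum(p)
  raw <- p * config$n_fish
  counts <- floor(raw)
  short <- config$n_fish - sum(counts)
  if (short > 0) {
    top <- order(raw - counts, seq_along(raw), decreasing = c(TRUE, FALSE),
                 method = "radix")[seq_len(short)]
    counts[top] <- counts[top] + 1
  }
  entries[seq_len(config$run_duration)] <- counts
  entries
}

#' Daily death counts from an entry schedule
#'
#' Every fish dies `lifespan` days after entering: `deaths[d] =
#' entries[d - lifespan]`. Totals are conserved; deaths falling beyond the
#' season are an error.
#'
#' @param entries Integer vector of per-day entry counts (length 90).
#' @param lifespan Days on the spawning grounds (>= 0).
#' @return Integer vector of per-day death counts, same length.
#' @export
death_schedule <- function(entries, lifespan) {
  if (lifespan < 0) stop("lifespan must be >= 0")
  n <- length(entries)
  deaths <- integer(n)
  src <- seq_len(n - lifespan)
  deaths[src + lifespan] <- entries[src]
  lost <- sum(entries) - sum(deaths)
  if (lost > 0) stop(sprintf("%d fish would die after the season ends", lost))
  deaths
}

#' Simulate the daily carcass dry-biomass trajectory
#'
#' Each day's deaths form a cohort entering the carcass pool at
#' `count * wet_mass * dry_fraction` kg dry. On every subsequent day each
#' cohort's mass is multiplied by `exp(predict_k(model, T))` at that day's
#' mean air temperature; the trajectory is the daily total over cohorts,
#' Dec 1 through Feb 28.
#'
#' @param config A [salmon_run_config()].
#' @param temps Daily mean air temperature, degrees C: a numeric vector of
#'   length 90, or a `weather_series` (the daylight-weighted mean of day and
#'   night temperature is used).
#' @param model A `decay_model`.
#' @return A `biomass_trajectory`: data.frame with columns `date`,
#'   `biomass` (kg dry), `cum_entries`, `cum_deaths`.
#' @export
simulate_carcass_biomass <- function(config, temps, model) {
  stopifnot(inherits(config, "salmon_run_config"), inherits(model, "decay_model"))
  dates <- winter_dates()
  n <- length(dates)
  if (inherits(temps, "weather_series")) temps <- daily_mean(temps)
  if (length(temps) < n) {
    stop(sprintf("temperature series has %d days; the season needs %d",
                 length(temps), n))
  }
  temps <- temps[seq_len(n)]
  entries <- entry_schedule(config)
  deaths <- death_schedule(entries, config$lifespan)
  m0 <- deaths * config$wet_mass * config$dry_fraction
  k <- predict_k(model, temps)
  biomass <- numeric(n)
  pool <- 0
  for (j in seq_len(n)) {
    pool <- pool * exp(k[j]) + m0[j]
    biomass[j] <- pool
  }
  out <- data.frame(date = dates, biomass = biomass,
                    cum_entries = cumsum(entries),
                    cum_deaths = cumsum(deaths))
  class(out) <- c("biomass_trajectory", "data.frame")
  out
}

#' Seasonal summaries of a biomass trajectory
#'
#' @param traj A `biomass_trajectory` covering the full season.
#' @return List with `final_biomass` (kg dry on Feb 28), `season_sum`
#'   (kg x days, the sum of daily biomass over all 90 days), and
#'   `peak_day` (season day index of maximum biomass; `NA` for an
#'   all-zero trajectory).
#' @export
seasonal_summary <- function(traj) {
  stopifnot(inherits(traj, "biomass_trajectory"))
  b <- traj$biomass
  list(
    final_biomass = b[length(b)],
    season_sum = sum(b),
    peak_day = if (all(b == 0)) NA_integer_ else which.max(b)
  )
}

#' Percent biomass reduction between two trajectories
#'
#' Compares a baseline and a warmed trajectory on the same date grid:
#' `100 * (base - warm) / base` for the final-day and the season-summed
#' biomass. Positive values mean less biomass under warming.
#'
#' @param traj_base,traj_warm `biomass_trajectory` objects on identical
#'   dates.
#' @return List with `final_pct` and `season_sum_pct`.
#' @export
compare_decades <- function(traj_base, traj_warm) {
  stopifnot(inherits(traj_base, "biomass_trajectory"),
            inherits(traj_warm, "biomass_trajectory"))
  if (!identical(as.Date(traj_base$date), as.Date(traj_warm$date))) {
    stop("trajectories must share the same date grid")
  }
  sb <- seasonal_summary(traj_base)
  sw <- seasonal_summary(traj_warm)
  if (sb$final_biomass == 0 || sb$season_sum == 0) {
    stop("baseline biomass is zero; percent change undefined")
  }
  list(
    final_pct = 100 * (sb$final_biomass - sw$final_biomass) / sb$final_biomass,
    season_sum_pct = 100 * (sb$season_sum - sw$season_sum) / sb$season_sum
  )
}
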