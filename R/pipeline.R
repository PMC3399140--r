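# Factorial scenario grid: climate models x sites x decades x years.
# One cell = one simulated winter driving both the eagle consumption model
# and the carcass-biomass simulation.

#' Define the scenario grid
#'
#' @param models Model-analog labels (default `"A"`, `"B"`).
#' @param sites Site labels.
#' @param decades Decade labels.
#' @param years Simulated winters per decade.
#' @param base_seed Integer; per-cell seeds are derived from it and the
#'   cell labels so any cell is reproducible in isolation.
#' @return A `scenario_grid`.
#' @export
scenario_grid <- function(models = c("A", "B"),
                          sites = c("Skagit", "HammaHamma", "Nisqually"),
                          decades = c("1970s", "2050s"),
                          years = 10, base_seed = 1) {
  stopifnot(years >= 1, length(models) >= 1, length(sites) >= 1,
            length(decades) >= 1)
  structure(list(models = models, sites = sites, decades = decades,
                 years = years, base_seed = base_seed),
            class = "scenario_grid")
}

# Deterministic per-cell seed: polynomial string hash of the labels folded
# into the base seed, kept below 2^31.
cell_seed <- function(base_seed, model, site, decade, year) {
  key <- paste(model, site, decade, year, sep = "|")
  h <- as.double(base_seed) %% 2147483647
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run the full scenario grid
#'
#' For every cell (model x site x decade x year) the matching preset
#' climate scenario is seeded and one winter of weather is generated; the
#' eagle bioenergetics model and the carcass-biomass simulation are run on
#' it. The same base seed reproduces the full grid bit-identically.
#'
#' @param grid A [scenario_grid()].
#' @param scenarios Named list of [climate_scenario()] presets keyed
#'   `"<site>_<decade>_<model>"`; defaults to [default_scenarios()].
#' @param decay A `decay_model`; defaults to the fit to the shipped
#'   [decay_observations()].
#' @param eagle An [eagle_model()].
#' @param run A [salmon_run_config()].
#' @return A `scenario_results` list, one element per cell, each holding
#'   the cell labels, seed, the `weather` series, the `consumption`
#'   ([season_consumption()]) and `trajectory`
#'   ([simulate_carcass_biomass()]) objects, and the seasonal summaries.
#' @export
run_scenario_grid <- function(grid, scenarios = default_scenarios(),
                              decay = fit_decay_model(decay_observations()),
                              eagle = eagle_model(),
                              run = salmon_run_config()) {
  stopifnot(inherits(grid, "scenario_grid"))
  results <- list()
  for (m in grid$models) for (s in grid$sites) for (d in grid$decades) {
    key <- paste(s, d, m, sep = "_")
    sc <- scenarios[[key]]
    if (is.null(sc)) stop(sprintf("no preset scenario for cell %s", key))
    for (y in seq_len(grid$years)) {
      seed <- cell_seed(grid$base_seed, m, s, d, y)
      res <- tryCatch({
        weather <- generate_winter_weather(sc, seed = seed)
        cons <- season_consumption(eagle, weather)
        traj <- simulate_carcass_biomass(run, weather, decay)
        list(model = m, site = s, decade = d, year = y, seed = seed,
             weather = weather, consumption = cons, trajectory = traj,
             summary = seasonal_summary(traj))
      }, error = function(e) {
        stop(sprintf("cell %s year %d: %s", key, y, conditionMessage(e)),
             call. = FALSE)
      })
      results[[length(results) + 1L]] <- res
    }
  }
  structure(results, class = "scenario_results")
}

#' One-row-per-cell summary table
#'
#' @param results A `scenario_results`.
#' @return data.frame with cell labels, seed, winter mean temperature and
#'   total precipitation, eagle season totals, and carcass-biomass
#'   summaries.
#' @export
summary_table <- function(results) {
  stopifnot(inherits(results, "scenario_results"))
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      model = r$model, site = r$site, decade = r$decade, year = r$year,
      seed = r$seed,
      t_mean_C = mean(daily_mean(r$weather)),
      precip_total_mm = sum(r$weather$precip),
      consumption_kJ = r$consumption$total_kJ,
      consumption_g = r$consumption$total_g,
      final_biomass_kg = r$summary$final_biomass,
      season_sum_kg_days = r$summary$season_sum,
      peak_day = r$summary$peak_day
    )
  }))
}

#' Tidy monthly means per grid cell
#'
#' Long-format table of December, January, and February means of daily
#' mean air temperature, daily precipitation, and daily eagle consumption
#' — the table monthly-scale statistics (ANOVA and the like) consume.
#'
#' @param results A `scenario_results`.
#' @return data.frame with columns `model`, `site`, `decade`, `year`,
#'   `month` (`Dec`/`Jan`/`Feb`), `variable`
#'   (`temperature_C`/`precip_mm`/`consumption_kJ`), `value`. One row per
#'   cell x month x variable.
#' @export
monthly_means <- function(results) {
  stopifnot(inherits(results, "scenario_results"))
  month_label <- c("12" = "Dec", "01" = "Jan", "02" = "Feb")
  do.call(rbind, lapply(results, function(r) {
    mo <- month_label[format(as.Date(r$weather$date), "%m")]
    vars <- list(
      temperature_C = daily_mean(r$weather),
      precip_mm = r$weather$precip,
      consumption_kJ = r$consumption$daily$c_kJ
    )
    do.call(rbind, lapply(names(vars), function(v) {
      agg <- tapply(vars[[v]], mo, mean)
      data.frame(model = r$model, site = r$site, decade = r$decade,
                 year = r$year, month = c("Dec", "Jan", "Feb"),
                 variable = v, value = unname(agg[c("Dec", "Jan", "Feb")]),
                 row.names = NULL)
    }))
  }))
}

#' Decade contrasts and final-biomass proportions
#'
#' Averages each metric over years within (model, site, decade), then
#' reports the percent change `100 * (past - future) / past` per site and
#' model for mean eagle season consumption, final-day carcass biomass, and
#' season-summed carcass biomass (positive = lower under the future
#' decade). Also emits final-biomass proportions relative to the reference
#' site within each model/decade block.
#'
#' @param results A `scenario_results` holding both decades for every
#'   site/model.
#' @param past,future Decade labels to contrast.
#' @param reference_site Site the biomass proportions are scaled to.
#' @return List of two data.frames: `contrasts` (`model`, `site`,
#'   `metric`, `pct_decline`) and `proportions` (`model`, `decade`,
#'   `site`, `final_biomass_kg`, `proportion`).
#' @export
decade_contrast <- function(results, past = "1970s", future = "2050s",
                            reference_site = "HammaHamma") {
  tab <- summary_table(results)
  if (!all(c(past, future) %in% tab$decade)) {
    stop(sprintf("both decades ('%s', '%s') must be present", past, future))
  }
  agg <- stats::aggregate(
    tab[, c("consumption_kJ", "final_biomass_kg", "season_sum_kg_days")],
    by = tab[, c("model", "site", "decade")], FUN = mean
  )
  metrics <- c("consumption_kJ", "final_biomass_kg", "season_sum_kg_days")
  contrasts <- list()
  for (m in unique(agg$model)) for (s in unique(agg$site)) {
    p <- agg[agg$model == m & agg$site == s & agg$decade == past, ]
    f <- agg[agg$model == m & agg$site == s & agg$decade == future, ]
    if (nrow(p) != 1L || nrow(f) != 1L) {
      stop(sprintf("site %s / model %s missing a decade", s, m))
    }
    for (met in metrics) {
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        model = m, site = s, metric = met,
        pct_decline = 100 * (p[[met]] - f[[met]]) / p[[met]]
      )
    }
  }
  proportions <- list()
  for (m in unique(agg$model)) for (d in unique(agg$decade)) {
    block <- agg[agg$model == m & agg$decade == d, ]
    ref <- block$final_biomass_kg[block$site == reference_site]
    if (length(ref) != 1L) {
      stop(sprintf("reference site %s absent from model %s / decade %s",
                   reference_site, m, d))
    }
    proportions[[length(proportions) + 1L]] <- data.frame(
      model = m, decade = d, site = block$site,
      final_biomass_kg = block$final_biomass_kg,
      proportion = block$final_biomass_kg / ref
    )
  }
  list(contrasts = do.call(rbind, contrasts),
       proportions = do.call(rbind, proportions))
}
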