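# eaglewinter

Thousands of bald eagles (*Haliaeetus leucocephalus*) overwinter around
Puget Sound to scavenge chum salmon (*Oncorhynchus keta*) carcasses.
Winter warming acts on this system twice: it barely changes what an eagle
must eat (metabolic demand), but it sharply accelerates how fast dead
salmon rot away (food supply). `eaglewinter` is a simulation pipeline for
quantifying that asymmetry. It is written for ecologists and
climate-impact modellers who want a tested, seeded, fully configurable
version of the winter climate → carcass decay → eagle energy-budget chain.

## The models

**Carcass decomposition.** Dry mass decays exponentially,
`W_t = W_0 · e^(k·t)`, with the daily rate `k = ln(W_t/W_0)/t` (day⁻¹,
negative for mass loss). Nine published salmonid decay observations
(−0.5 to 16 °C, air and water exposure) give the fitted temperature
response

```
k = −0.0072 − 0.0032·T     (r² = 0.80, n = 9)
```

clamped at zero below −2.2 °C so cold can stall decay but never reverse
it.

**Salmon run.** A hypothetical run of 40,560 chum (3.652 kg each, 16% dry
matter) enters from December 1 over 10 weeks with normally distributed
timing, lives 10 days on the spawning grounds, then joins the carcass
pool. Each day every cohort is multiplied by `e^(k(T))` at that day's mean
air temperature and the pool is summed, December 1 – February 28.

**Eagle bioenergetics.** A 4.5-kg eagle eats enough carcass each day to
hold constant mass. Mass-specific daily expenditure is the
activity-weighted sum

```
E = F_GB·M_day(active) + F_P·M_day(rest) + F_R·M_night(rest)
    + F_AF·12.5·BMR + F_PF·3.5·BMR
```

over gravel-bar feeding, daytime perching, nighttime roosting, and
flapping/gliding flight, with roosting pinned to the dark hours by
photoperiod. `M` is standard metabolic rate (BMR above the 10 °C lower
critical temperature, rising linearly below) plus wind, precipitation,
and longwave-radiation-deficit surcharges. Consumption in grams is
`E · mass / WME` with diet energy density WME = 3.764 kJ per gram wet
mass.

**Synthetic climate.** Because the original downscaled regional-climate
fields are not redistributable, a seeded generator emulates their
structure: site mean temperature + month-specific decade warming + AR(1)
daily anomalies, day/night split by photoperiod; Bernoulli×gamma
precipitation; Weibull wind; longwave flux as effective emissivity times
σT⁴ with cloud cover correlated with precipitation. Twelve presets span 3
rivers (Skagit, Hamma Hamma, Nisqually) × 2 decades (1970s, 2050s) × 2
model analogs.

## Worked example

```r
library(eaglewinter)

fit <- fit_decay_model(decay_observations())
fit
#> <decay_model> k = -0.0072 + -0.0032 * T  (r^2 = 0.80, n = 9)

w <- generate_winter_weather(
  climate_scenario(site = "Skagit", latitude = 48.4, t_mean = 3.6, seed = 1))
traj <- simulate_carcass_biomass(salmon_run_config(), w, fit)
seasonal_summary(traj)
#> $final_biomass: 9447 kg dry on Feb 28
#> $season_sum:    672828 kg·days over the 90-day winter
#> $peak_day:      60 (late January)

season_consumption(eagle_model(), w)
#> <season_consumption> 144194 kJ, 38309 g (10.5 carcass-equivalents) over 90 days

warm <- climate_scenario(site = "Skagit", latitude = 48.4, t_mean = 3.6,
                         t_offset = c(1, 2.5, 2.5), seed = 1)  # 2050s-style warming
tw <- simulate_carcass_biomass(salmon_run_config(),
                               generate_winter_weather(warm), fit)
compare_decades(traj, tw)
#> $final_pct:      28.2   # 28% less carcass left on Feb 28
#> $season_sum_pct: 13.4   # 13% less carcass-days over the winter
```

One warmed winter removes ~13% of the season's carcass biomass while the
same warming trims the eagle's energy budget by only a few percent — the
climate signal reaches the eagles through their food, not their
metabolism.

## The analysis workflow

Numbered drivers under `analysis/` run the full study and write tables to
`results/`:

| script | what it does |
| --- | --- |
| `01_fit_decay.R` | fits the temperature→k regression, saves coefficients |
| `02_generate_weather.R` | one example winter per preset, site/decade summary |
| `03_run_grid.R` | the 120-simulation factorial grid (2 models × 3 sites × 2 decades × 10 winters); per-cell summaries and the tidy 360-row-per-variable monthly table |
| `04_decade_contrasts.R` | decade percent-declines per site/model, final-biomass proportions, and the controlled +2.5 °C paired-seed warming experiment |

Each is a thin narrative wrapper over package functions; everything is
deterministic given the base seed in the script.

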