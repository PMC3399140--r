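---
title: "Models and methods: winter climate, carcass decay, and eagle energy budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: winter climate, carcass decay, and eagle energy budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eaglewinter)
```

`eaglewinter` chains four models: a synthetic winter climate generator, a
temperature-driven carcass decomposition model, a chum salmon run
simulator, and an eagle daily-consumption energy budget. This vignette
documents each model's assumptions, its tunable parameters, and the
numerical and design choices behind them — including the places where the
design was genuinely open and this package had to decide.

## The winter season

All simulations run on a fixed 90-day season, December 1 – February 28,
the months when overwintering eagles concentrate on Puget Sound chum
runs. February 29 is never emitted, even in leap years: decade
comparisons need trajectories that align day-for-day, and one extra day
per simulated leap winter would buy realism nobody uses at the cost of
ragged arrays everywhere. `winter_dates()` uses a non-leap reference
winter for the same reason.

## Synthetic climate generation

The original study drove its models with hourly downscaled
regional-climate output, which is not redistributable. The generator
emulates the *statistical structure* of such output at the resolution the
downstream models actually consume — daily values with a day/night split —
rather than attempting hourly dynamics.

Daily mean temperature is

$$T_d = \mu + \Delta_{m(d)} + a_d, \qquad a_d = \phi\, a_{d-1} + \varepsilon_d$$

with site mean $\mu$, month-specific decade warming offsets
$\Delta_{m}$, and AR(1) anomalies. Defaults: $\phi = 0.7$ and marginal
anomaly SD 3 °C, which mimic multi-day synoptic persistence without
modelling fronts. **A note on "anomaly SD":** the generator interprets it
as the *stationary* (marginal) SD of the anomaly process; innovations get
SD $\sigma\sqrt{1-\phi^2}$ and the initial anomaly is drawn from the
stationary distribution. The alternative (innovation-SD) reading would
inflate the marginal spread by $1/\sqrt{1-\phi^2} \approx 1.4$; decade
*contrasts* are nearly indifferent to the choice because the decay
exponent is linear in temperature, but the marginal variance is not, so
the convention is fixed and stated here.

The day/night split conserves the daylight-weighted daily mean exactly:

$$T_{day} = T_d + \delta\,(1 - h/24), \qquad T_{night} = T_d - \delta\,h/24$$

with photoperiod $h$ and diurnal half-range $\delta$ (default 2 °C). Any
weighted recombination $\left[h\,T_{day} + (24-h)\,T_{night}\right]/24$
returns $T_d$, so the carcass model (which consumes the weighted mean)
sees the configured temperature process unchanged.

Precipitation is wet-day occurrence (Bernoulli, default p = 0.5–0.7 by
site) times a gamma amount (shape 0.8; scale 5–10 mm by site): an
intermittent, right-skewed daily series, the standard minimal stochastic
weather-generator form. Wind is Weibull (shape 2, scale 4 m s⁻¹).
Downward longwave flux is a bulk emissivity model,
$\varepsilon_{e\!f\!f}\,\sigma T_K^4$ with
$\varepsilon_{e\!f\!f} = \varepsilon_{clear} + \Delta\varepsilon\, c$
(defaults 0.70 + 0.20·cloud), cloud fraction drawn daily and shifted up
on wet days — enough to give the physically right covariation (warm
cloudy wet nights lose less heat) without a radiation scheme.

Draw order is fixed and the number of variates consumed per winter does
not depend on parameter values, so two scenarios differing only in a
deterministic parameter (a warming offset, say) share identical anomalies
under the same seed. That is what makes paired-seed warming experiments
exact: the +2.5 °C run *is* the baseline run, shifted.

### Presets

`default_scenarios()` provides 3 sites × 2 decades × 2 model analogs.
Site latitudes (Skagit 48.40°N, Hamma Hamma 47.55°N, Nisqually 47.10°N)
are approximate river-mouth values and matter only through photoperiod.
Site means (3.0–4.4 °C, model analog B 0.8 °C colder) encode the
qualitative ordering reported for these basins — Nisqually warmest, Hamma
Hamma coldest, Nisqually clearly driest — and the decade offsets
(+1.0 °C December, +2.5 °C January/February) encode warming concentrated
in late winter, with slightly lower cloud in the 2050s. The magnitudes
are calibrated choices of this package: the source fields were published
only graphically, so no preset number should be read as a measured value.
They were chosen once, from the qualitative description, and are fully
overridable.

### What the generator does *not* emulate

No spatial correlation between sites, no wet/dry spell persistence beyond
what AR(1) temperature induces, no temperature–precipitation correlation,
no trends within a winter, no extremes beyond what gamma tails produce.
Tests passing on this generator therefore demonstrate that the *pipeline*
responds correctly to imposed climate contrasts; they do not validate the
generator against real meteorology.

## Photoperiod

`daylight_hours()` is the standard sunrise-equation day length with solar
declination $\delta = 23.45°\sin(2\pi(284+N)/365)$ and a solar zenith of
90.833° (refraction plus solar-disk radius), matching NOAA-style solar
calculators to within a couple of minutes at mid-latitudes. Latitudes
outside (0°, 66°N) are rejected rather than clamped: polar day/night
would silently break the day/night weighting downstream.

## Carcass decomposition

Dry mass decays exponentially with daily rate $k \le 0$ (day⁻¹), and
$k$ is modelled as linear in temperature by unweighted OLS over nine
published salmonid observations, pooling air and water exposure (the
exposure label is kept as metadata). The shipped fit is

```{r}
fit <- fit_decay_model(decay_observations())
fit
```

Numerical choices:

* **Sign convention.** `k` is stored negative (mass loss) everywhere;
  `apply_decay()` rejects positive rates rather than guessing intent.
* **Cold clamp.** The fitted line crosses zero near −2.2 °C; below that,
  `predict_k()` returns 0. Unclamped, cold days would *grow* carcasses.
  Physically, decay stalls in frost; the data contain one sub-zero
  observation consistent with near-zero loss.
* **OLS specifics.** Plain unweighted least squares on the raw scale —
  the simplest fit reproduces the published coefficients at their
  printed precision, so no transformation or weighting is assumed. The
  fit is cross-checked in the test suite against hand-rolled normal
  equations to 10⁻¹².

## The salmon run

Defaults: 40,560 fish, 3.652 kg wet each, 16% dry matter, entering from
December 1 over 70 days, dying after 10 days on the spawning grounds.
Entry timing is a truncated normal over the 10-week window. Its mean
(day 35) and SD (70/6 days) are this package's choice: the source states
only "normally distributed" over 10 weeks, so the window is centred and
±3 SD spans it. Both are configurable.

* **Integerization.** Daily entry probabilities are converted to whole
  fish by largest-remainder apportionment (ties broken by earlier day),
  so entries sum to the run size *exactly* — the conservation identity
  `final biomass = n · wet · dry` under `k = 0` holds to 10⁻⁹ relative,
  and is an acceptance check. The price is that biomass is linear in run
  size only up to ±1 fish per day; exact multiplicative linearity holds
  through per-fish mass instead.
* **Cohort merging.** All fish dying the same day form one cohort; under
  a shared daily `k` this is exact and keeps the simulation at 90×90.
* **Update order.** On its death day a cohort enters at full mass and
  first decays the following day; the day-loop then matches the closed
  form $\sum_d m_0(d)\,e^{k\,(end-d)}$ at constant temperature to 10⁻⁹
  relative (a second acceptance check).
* **Driving temperature.** The daylight-weighted mean of day and night
  air temperature — air, not water, because the eagles' accessible
  carcasses are the ones out of the water.

## Eagle bioenergetics

Daily mass-specific expenditure is the activity-weighted sum over five
states — gravel-bar feeding/waiting (active SMR, day weather), daytime
perching (resting SMR, day weather), nighttime roosting (resting SMR,
night weather), flapping flight (12.5 × BMR) and gliding flight
(3.5 × BMR) — and intake is expenditure divided by diet energy density
(constant body mass). This *term structure* is fixed; the sub-model
constants are configuration:

| parameter | default | units | rationale |
| --- | --- | --- | --- |
| mass | 4.5 | kg | adult bald eagle |
| WME | 3.764 | kJ g⁻¹ wet | salmon carcass energy density; see note |
| BMR allometry | 327.6·M^0.723 | kJ day⁻¹ | standard non-passerine allometry (≈216 kJ kg⁻¹ day⁻¹ at 4.5 kg) |
| t_lc | 10 | °C | lower critical temperature |
| cold slope | 6 | kJ kg⁻¹ day⁻¹ °C⁻¹ | linear thermoregulatory cost below t_lc (~40% over BMR at −5 °C) |
| wind coeff | 5 | kJ kg⁻¹ day⁻¹ per m s⁻¹ | convective surcharge |
| precip coeff | 1.5 | kJ kg⁻¹ day⁻¹ per mm | plumage-wetting surcharge |
| rad coeff | 0.3 | kJ kg⁻¹ day⁻¹ per W m⁻² | cost of longwave deficit below the ε=0.85 reference flux |
| activity mult | 2 | — | active vs resting standard metabolism |
| flight mults | 12.5 / 3.5 | ×BMR | flapping / gliding |
| daylight shares | 0.35 / 0.55 / 0.04 / 0.06 | — | gravel bar / perch / flapping / gliding; all dark hours roost |

**The WME unit.** Printed diet energy densities of "3.764 kJ·kg⁻¹" are
dimensionally inconsistent with daily intakes of a few hundred grams at
~10³ kJ day⁻¹ expenditure (they would imply ~400 kg of salmon a day).
The package reads the value as kJ per **gram** wet mass, which yields
plausible intakes (~400 g day⁻¹); the discrepancy is flagged rather than
silently corrected, and `wme` is configurable.

**Linear surcharges.** The wind, precipitation, and radiation terms are
deliberately linear and additive: the pipeline's claims are directional
(warmer/drier → slightly cheaper winters), and a monotone surcharge model
supports exactly those claims while staying fully inspectable. One known
consequence: above `t_lc`, metabolic heat can *rise* slightly with
temperature through the growing reference longwave flux; below `t_lc`
(i.e., essentially all simulated winter days) the 6 kJ kg⁻¹ day⁻¹ °C⁻¹
cold slope dominates the ~1.2 kJ kg⁻¹ day⁻¹ °C⁻¹ reference-flux drift
and consumption is strictly decreasing in temperature.

**What is not reproduced.** The original model's exact sub-model algebra
and constants live in prior work that prints neither; consequently this
package's absolute consumption values (and its "<1 %" style decade
declines, which come out nearer 2–4 % under the default surcharges and
synthetic winters) are not comparable number-for-number with the
original. The pipeline's bioenergetics claims are therefore directional
and structural — monotone responses, component conservation, and a demand
effect far smaller than the supply effect — and are tested as such.

## The scenario grid

The full experiment is 2 model analogs × 3 sites × 2 decades × 10 winters
= 120 simulated winters. Per-cell seeds are a deterministic polynomial
hash of the cell labels folded into the base seed (kept below 2³¹), so
any single cell can be regenerated in isolation and the whole grid is
bit-reproducible. Decades use *independent* seeds by default — the grid
hash includes the decade label — because pairing internal variability
across decades is an analysis choice, not a fact about the climate;
paired-seed experiments are still available directly (generate two
scenarios with the same seed), and that is how the controlled +2.5 °C
experiment is run.

Monthly means (temperature, precipitation, consumption; 120 cells × 3
months = 360 rows per variable) are emitted as a tidy long table. The
downstream ANOVA/post-hoc machinery of the original analysis is
deliberately out of scope: it is routine off-the-shelf statistics, and
the table is the contract.

## Problem sizes

The test suite and acceptance script run, by design, at the study's own
scales: 90-day winters, the 40,560-fish run, the 120-cell grid (about
3 s), 20-winter warming ensembles, and a 1000-winter convergence check
for the generator mean (~5 s). Nothing is scaled down from the study
design.

## Known limitations

* Eagle consumption does not feed back on the carcass pool; supply and
  demand are compared, not coupled (as in the original design).
* No river-flow effects on carcass availability, no energy-density
  decline with carcass age, no prey switching or demography.
* The climate generator's realism limits are listed above; in particular
  precipitation decade contrasts are imposed, not emergent.
* The decay regression pools heterogeneous studies (species, exposure,
  scavenger access); it is representative of the temperature response,
  not calibrated for any single river.
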