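---
title: "Degree-day modeling of first-flight phenology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day modeling of first-flight phenology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firstflight)
library(dplyr)
```

## The model

`firstflight` models the first flight (FF) of a spring insect as a
heat-sum event. The working hypothesis is that a species needs a fixed
cumulative amount of development heat — a degree-day constant DD~C~ — above
a base temperature T~0~, and that this constant is a property of the
species' physiology rather than of any particular region or climate. If
that holds, the *timing* of FF varies across space and years only because
the climate that delivers the heat varies, and a constant calibrated in one
region's climate is transferable to another's, including a future one.

The daily degree-day contribution is computed from gridded daily maximum
and minimum temperature with a four-branch weighted formula (see
`daily_delta_dd()`): zero when T~max~ stays below the threshold, the full
excess of the daily mean when even T~min~ clears it, and fractional weights
(0.5 on the T~max~ excess, 0.25 penalties/credits on the side that
straddles the threshold) for intermediate days. The formula is continuous
across its branch boundaries and non-negative for any physically valid
input (T~max~ ≥ T~min~); both properties are enforced by property-style
tests. Branch selection uses exact comparisons with no epsilon: the
branches agree at every boundary, so ties are harmless.

Contributions are accumulated per grid cell from January 1 with no
carry-over between years (`accumulate_dd()`); February 29 is a real day and
is included, so series have length 365 or 366. The per-cell series are then
averaged *day-wise over degree-day values* across the member cells of a
region (`regional_average_dd()`). Averaging degree-days, not temperatures,
matters: the degree-day transform is nonlinear, and the distinct quantity
"degree-days of the mean temperature" is deliberately not computed.

The modeled regional FF of a year is the first day the regional cumulative
series reaches DD~C~ (`first_crossing()`): a first-crossing rule with no
sub-day interpolation, ties at exact equality taking the first qualifying
day. Years that never reach the constant return a not-reached marker (`NA`)
rather than an error.

## Observations and the two bracketing assumptions

Citizen-science sighting records carry two entangled sources of intra-cell
scatter: genuine sub-grid (microclimate) variability, and reporting delay.
The package treats them as bracketing cases rather than attempting a mixed
model:

* **SVA** (spatial variability assumption): every deduplicated sighting is
  a correct, spatially variable FF date; all records in a cell enter.
* **OBA** (observation bias assumption): only the earliest sighting per
  cell and year is correct; everything later is delay.

Before either view is built, records are reduced to one per location and
year — the earliest (`dedupe_location_year()`), location identity being
exact (lon, lat) equality; no spatial fuzzing is attempted because nothing
in the data supports choosing a radius. Under OBA, two locations tied on
the earliest date are indistinguishable for the model and collapse to one
observation. Summary statistics (`ff_summary_stats()`) decompose the data
three ways — all observations, per-cell temporal means, per-year regional
means — using sample (n − 1) standard deviations, with single-member
groups reported as SD 0.

## Calibration

`calibrate_ff_model()` scans candidate constants on a 1-degree-day grid
(calibrated constants are conventionally reported as integers; the step is
configurable) and minimizes the RMSE in days between modeled and observed
regional annual mean FF over all years with data. The default search
bracket is the *primary range*: for each observation, the regional
cumulative series is evaluated at the observed FF day; per-year means of
those values give a min/mean/max over years, extended by 20% on each side.
This bracket is cheap, data-driven, and in practice contains the optimum —
a property the test suite checks on synthetic truth. If the arg-min
nevertheless lands on a search boundary, the range is extended once (with a
warning) and the condition flagged.

Numerical conventions, all covered by contract tests:

* Candidates for which more than half of the years never reach the
  constant are marked invalid and excluded from the arg-min; candidates
  unreachable in every year get infinite RMSE.
* Equal-RMSE ties resolve to the smaller constant; across base-temperature
  scenarios, the global best breaks ties toward smaller T~0~, then smaller
  DD~C~. One consequence worth knowing: when observations are exactly
  consistent with the model (RMSE 0), the zero-RMSE set is a plateau of
  constants that cross on the same days in every year, and the reported
  constant is that plateau's lower edge — with few years it can sit a few
  degree-days below the generating truth. This is the tie rule working as
  specified, not an estimation error.
* Calibration defaults to the three exemplified base temperatures
  T~0~ ∈ {0, 5.5, 10} °C, which span the experimentally plausible range;
  `t0_scan()` produces the full 0–10 °C by 0.5 °C table (21 scenarios) for
  the portable regional degree-day artifact.

Cross-regional agreement of the per-region best constants is summarized by
`consistency_metrics()` as the mid-range (min + max)/2 and the half-range
as a percentage of it, rounded to integer percent for reporting with the
unrounded value retained. `point_test()` evaluates the calibrated regional
model against individual sightings, each compared to the first crossing of
its *own cell's* series: the point RMSE is expectedly larger than the
regional RMSE, since the regional series averages away spatial variance —
an ordering the acceptance suite verifies over replicates.

One ambiguity deserves a note: the primary range is defined here by
evaluating the *regional* cumulative series at each observation's FF day.
The alternative reading — each observation's own cell series — gives a
slightly wider bracket; since the bracket only seeds the search and the
search extends itself when needed, the choice is not consequential for the
calibrated optimum.

## Two-period change assessment

`assess_change()` combines, per calibrated model: period mean modeled FF
dates (years not reaching the constant are excluded and counted),
their difference as days of advancement (positive = earlier under
warming), the change in regional mean daily temperature, and — via
`period_dd_change()` — the change in degree-days accumulated to fixed
windows (to July 31, day 212/213, and the whole year). Period means over a
mid-range constant are bracketed by the means at the range-limit constants
exactly (first-crossing dates are monotone in DD~C~); the *advancement*,
being a difference of two such means, inherits that bracketing only up to
the one-day quantization of crossing dates, and the tests allow that one
day of slack.

The qualitative structure this machinery is designed to expose: a warm
region whose temperatures hover near or above T~0~ converts almost all of
a small warming into new degree-days, while a cold region wastes most of a
larger warming on days that stay below threshold. Advancement then orders
*opposite* to the temperature rise and *with* the fixed-window degree-day
gain. The scenario test encodes exactly this ordering (a warm maritime
region with a damped seasonal cycle and +0.8 °C against a cold continental
one with a strong cycle and +1.2 °C), asserting orderings, never specific
days.

## The synthetic-data generator

`climate_scenario()` + `simulate_temperature()` emulate the structure of a
blended gridded daily product: a cosine seasonal cycle (period 365.25 days
for cross-year phase stability; the choice leaves a sub-0.01 °C residual
in single-year means, visible only to exactness tests), a linear
latitudinal gradient around the grid's mean latitude, a constant diurnal
range split symmetrically into tmax/tmin, and an optional step warming from
a change year onward — a step, not a trend, so two-period contracts are
exact. Weather noise is a region-wide daily anomaly (synoptic systems are
far larger than a 0.25° cell) plus optional independent per-cell noise;
the region-wide term is what gives years distinct accumulation histories
and makes the calibration identifiable, while spatially *correlated-but-
not-identical* noise fields are out of scope. Defaults (amplitude 11 °C,
diurnal range 7 °C, daily noise 2 °C) are chosen to look like southern
Scandinavia; the packaged `swedish_transect()` ships three 3 × 3-cell
regions with annual means 8.2, 6.9 and 3.6 °C spanning a steep gradient.

`simulate_sightings()` generates the two observation mechanisms with known
truth. SVA observers watch fixed locations with persistent microclimate
offsets N(0, σ), σ = 0.5 °C by default — offsets are time-constant by
design (microclimate, not weather) — and report the first crossing on the
offset series. OBA observers report the true cell FF plus an independent
non-negative delay, by default geometric on {0, 1, 2, …} with mean 3 days:
mass at zero makes the earliest-sighting estimator consistent, which is
exactly the property the OBA aggregation relies on (a discretized
exponential is selectable). The magnitudes of both noise sources are
user-facing parameters, not hidden constants, because no field
measurements pin them down. Every truth record stores the generating
configuration and the per-cell-year true FF, and a test verifies it
against an independent first-crossing oracle.

What passing tests on this generator do **not** show about real data: the
generator has no spatially structured observer effort, no seasonality in
reporting behavior, no missing-data patterns, and its FF dispersion
(2–4 days spatiotemporal SD under default noise) is well below the
~14–16 days typical of real citizen-science FF records. Parameter-recovery
results therefore demonstrate the *estimator's* correctness and bias
behavior, not field-accuracy of any particular constant.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use deliberately desk-scale
configurations: 9–30 cells, 6–8 observation years, 60-year climate records
for change assessment, 10–20 simulation replicates for stochastic
properties. These sizes keep every property measurably sharp (e.g. the
noisy-calibration bias bound of 5 degree-days at σ = 0.5 °C) while running
in well under an hour on a single core. All randomness flows from explicit
seeds: scenarios and observer models are bit-reproducible, and the
file-writing pipeline (`run_simulation()`, `run_calibration()`,
`run_change()`) writes a manifest (config echo + package version + seed)
sufficient to reproduce its outputs byte-for-byte.

## Known limitations

* Only the four-branch daily formula is implemented; sine-wave or hourly
  integration methods would slot behind the same accumulation interface
  but are not provided.
* No uncertainty quantification on DD~C~ (e.g. bootstrap CIs) — the
  cross-regional half-range is the only spread measure reported.
* No photoperiod, chilling, or host-plant covariates: the model is
  single-threshold heat accumulation by construction.
* Temperature ingestion is the long-format CSV dialect plus grid-spec
  sidecar; gridded binary formats are expected to be converted upstream.
* Cell-years with any missing day are excluded outright (conservative, no
  gap-filling); with very patchy records this can discard more data than
  interpolation-based alternatives would.
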