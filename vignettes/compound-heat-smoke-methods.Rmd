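---
title: "Methods: joint effects of extreme heat and wildfire smoke on hospitalizations"
author: "heatsmoke package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint effects of extreme heat and wildfire smoke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Wildfire smoke episodes and extreme heat increasingly co-occur, and their
joint effect on acute health outcomes may exceed the sum of their separate
effects. `heatsmoke` implements a complete analysis pipeline for
estimating such joint effects on hospitalizations with a time-stratified
case-crossover design: exposure construction from gridded environmental
fields, matched-stratum cohort assembly, exact conditional-logistic
interaction modeling, and additive-scale interaction measures across a
4×4 grid of exposure lags. Because real hospitalization records of this
kind are confidential, the package also ships a synthetic-data generator
whose case series follows the same conditional-logistic law with known
coefficients, so every downstream stage can be validated against ground
truth.

## The model

Each hospitalization (the *case day*) is compared with 3–4 *referent
days*: all other days in the same calendar month and year that share its
day of week. Within stratum $i$ the log-odds of hospitalization are

$$\mathrm{logit}\,\Pr(Y=1\mid X) = \beta_{0i}
  + \beta_H X_{\mathrm{HEAT}} + \beta_S X_{\mathrm{SMOKE}}
  + \beta_{HS} X_{\mathrm{HEAT}} X_{\mathrm{SMOKE}},$$

where $X_{\mathrm{HEAT}}$ is a binary extreme-heat indicator and
$X_{\mathrm{SMOKE}}$ a continuous wildfire-influenced PM$_{2.5}$
concentration (µg/m³), each read at its own lag (0–3 days). Conditioning
on one event per stratum eliminates the $\beta_{0i}$: the contribution of
a stratum is $\exp(\eta_{\mathrm{case}})/\sum_r \exp(\eta_r)$, and the
package maximizes this exact conditional likelihood by Newton–Raphson
with analytic gradient and Hessian (start at $\beta = 0$, step-halving on
any likelihood decrease, convergence at max $|$score$| < 10^{-8}$ or
relative log-likelihood change $< 10^{-10}$). The design matrix has only
three columns, so the observed information is inverted directly;
monotone likelihoods (separation) are flagged as non-converged with a
diagnostic rather than allowed to diverge silently.

With a smoke increment $\delta$ (1 µg/m³ by default) the derived
measures are

* $OR_{01} = e^{\beta_H}$ (heat alone), $OR_{10} = e^{\beta_S\delta}$
  (smoke alone), $OR_{11} = e^{\beta_H + \beta_S\delta + \beta_{HS}\delta}$
  (joint);
* multiplicative interaction $= OR_{11}/(OR_{01}\,OR_{10}) = e^{\beta_{HS}\delta}$;
* $\mathrm{RERI} = OR_{11} - OR_{10} - OR_{01} + 1$, the relative excess
  risk due to interaction (additive scale);
* $\mathrm{AP} = \mathrm{RERI}/OR_{11}$, the attributable proportion:
  the fraction of jointly-exposed risk attributable to synergy.

The single-coefficient measures get Wald intervals on the log scale.
RERI and AP get delta-method intervals: the measure's analytic gradient
in $(\beta_H, \beta_S, \beta_{HS})$ propagated through the fit
covariance. AP's interval is computed on AP's own gradient directly, not
back-transformed from RERI, since AP is the primary reported scale.
P-values are two-sided normal; a one-sided column (`ap_p1`) is also
emitted because reporting conventions differ between studies.

Additive-interaction measures for a continuous exposure are only defined
relative to a stated contrast; $\delta$ is therefore an explicit
argument rather than a hidden convention, and doubling $\delta$ is
exactly equivalent to refitting with the smoke variable halved (a tested
invariant).

## Exposure construction

* **Wildfire-influenced PM$_{2.5}$.** For each grid cell and calendar
  day the *expected smoke-free* concentration is the mean of total
  PM$_{2.5}$ over all study years on that calendar day, restricted to
  days with no overhead smoke plume. If a calendar day has no smoke-free
  observation the window widens symmetrically (±1, ±2, … up to ±15 days
  on a circular 365-day calendar) until one is found; a cell smoky
  through a ±15-day window raises an error naming the cell. On days when
  a plume overlaps the cell *and* total PM$_{2.5}$ exceeds this
  baseline, the wildfire-influenced concentration is the excess;
  otherwise zero. The estimator behind "expected" is a plain mean — the
  simplest faithful choice; a seasonal smoother would be a defensible
  alternative but changes baselines by less than day-to-day noise on the
  synthetic fields. Feb 29 pools with Feb 28 so calendar-day keys are
  well-defined across leap years.
* **Population weighting.** Gridded hazard values are aggregated to ZIP
  Code Tabulation Areas as population-share weighted means
  ($\sum_c v_c\,p_c / \sum_c p_c$) — a convex combination, so ZCTA
  values are bounded by their member cells, and adding a constant to
  every cell shifts every ZCTA by exactly that constant (both tested).
  Nearest-neighbor regridding (block replication on nested grids)
  mirrors the resampling of a coarse product onto the fine analysis
  grid.
* **Extreme heat.** Thresholds are empirical percentiles (90th, 95th,
  99th) of daily maximum temperature pooled per (ZCTA, calendar month)
  across study years, with linear interpolation between order statistics
  (R quantile type 7). A day is an extreme-heat day when Tmax is
  *strictly greater* than its threshold; at the 95th percentile this
  flags 5% of days per pool up to interpolation error (at most one day),
  which the tests assert exactly. Temperatures are degrees Fahrenheit
  throughout.

## Cohort assembly

Records are assigned to ZCTAs by residential ZIP, falling back to the
hospital ZIP, and excluded (with counts) when neither maps or exposure
data are missing. Outcome groups (all-natural, respiratory,
cardiovascular, cerebrovascular, renal) are decided on the
three-character ICD category, so subcodes inherit their category's
classification; external-cause and injury codes classify to no outcome.
A record with several qualifying codes enters each outcome-specific
analysis once. Seasonal restriction (May–November) is decided on the
case date; referents share the month by construction. Lag look-backs may
cross the month boundary backwards (a May 2 case with lag 3 reads
April 29 exposure) because lags are exposure history, not design
constraints. Every run reports an accounting identity: input records =
analyzed + excluded at each gate.

## The synthetic-data generator

`generate_environment()` draws: daily maximum temperature as an annual
sinusoid peaking mid-July (default mean 75 °F, half-amplitude 20 °F,
Gaussian day-to-day noise SD 5 °F); lognormal background PM$_{2.5}$
(mean 8, SD 4 µg/m³); plume events per cell as Poisson multi-day runs
(default 2 events per May–November season, mean duration 3 days) that
add about 15 µg/m³ (±25% jitter); a static lognormal population surface;
and a crosswalk of contiguous ZCTA blocks on a rectangular grid. These
defaults are chosen to resemble a Californian setting — a ~5% heat-day
rate per month by construction of the percentile thresholds, and a small
percentage of smoke-exposed days — while remaining fast to simulate.
Demographic draws default to the composition of California natural-cause
admissions (41–58% split by sex, 40% aged 65+, 85% English speakers),
and community flags (high poverty 18.8%, low education 31.8%, rural
2.8%) are drawn once per ZCTA.

`simulate_cases()` inverts the analysis model: it picks a (ZCTA, year,
month, day-of-week) stratum uniformly among strata with ≥ 2 eligible
days, then picks the admission day within the stratum with probability
proportional to $\exp(\beta_H X_H + \beta_S X_S + \beta_{HS} X_H X_S)$
at the configured truth lags — exactly the conditional-logistic law the
fitter assumes, which makes parameter recovery exact in expectation.
Because the generator conditions on the same stratum definition the
analysis uses, recovery tests validate the estimator, not the referent
scheme; the referent scheme is tested separately by calendar
enumeration. `simulate_strata()` is a stripped stratum-level version of
the same law (i.i.d. exposures per day: heat Bernoulli 0.2, smoke a
0.25-probability Exponential with mean 2 µg/m³) used for replicated
recovery and coverage studies where the gridded pipeline would add cost
but no information; its exposure rates are chosen for adequate Fisher
information in all three coefficients at a few thousand strata.

What the generator does **not** emulate: spatially coherent weather
(cells are conditionally independent around the shared seasonal cycle),
realistic fire calendars, spatial autocorrelation of plumes across
cells, outcome-specific effect sizes, or confounding structures that the
case-crossover design is meant to remove. Passing tests therefore
demonstrate the correctness of the estimators and plumbing under the
assumed design, not robustness to violations of it.

## The study runner

`run_lag_grid()` fits all 16 lag pairs per outcome; `run_stratified()`
refits all three coefficients within each subgroup level (sex, age
group, language, race/ethnicity, and ZCTA-level binary flags: ≥ 25% of
households in poverty, ≥ 50% with at most high-school education, ≥ 50%
rural). Cells with fewer than 10 exposed cases are suppressed — counts
are kept, estimates are not. "Exposed" defaults to joint exposure
(heat day and smoke > 0 at the assigned lags), the binding constraint
for an interaction estimate; a permissive "either" rule is available
because the counting rule is a reporting convention, not an estimand.
Raw p-values are reported across all cells with the cell count, leaving
multiplicity adjustment to the reader. `write_report()` emits
per-outcome CSV tables of the AP grid (the tabular twin of a lag-grid
heat map), a complete JSON of estimates, and a run log with the
accounting identity. By default admission year 2020 is excluded
(pandemic-era hospital utilization); this is a config option, not a
hard-coded rule.

## Numerical choices and degenerate inputs

* Strata with no exposure contrast contribute a constant to the
  likelihood; they are dropped and counted, never silently included.
* A term with no within-stratum variation anywhere makes the
  information singular; the fit refuses and names the term.
* Group-wise max subtraction guards `exp` overflow in the likelihood.
* Quantile ties (constant temperature) give identical thresholds at all
  percentiles; the strict `>` flag then marks zero heat days, which is
  the correct degenerate answer.
* Dates are keyed on a fixed 365-day calendar for baselines; all other
  logic uses true calendar dates.

## Problem sizes used in validation

The shipped tests validate the likelihood against exhaustive enumeration
and central differences on 1,000 random small strata; coefficient
recovery and CI coverage over 200 replicates of 5,000 strata; the
delta-method intervals against a 2,000-draw parametric bootstrap on 20
fits of 8,000 strata; lag localization over 50 replicates of 1,000 cases
on a 6×6-cell, 4-ZCTA, 2-year world; and the referent scheme on 10,000
random dates. These sizes give Monte-Carlo error well inside the asserted
tolerances while keeping a full run in a few minutes on one CPU.

## Known limitations

* The smoke-free baseline is an unsmoothed calendar-day mean; with very
  few years of data it is noisy, and the window-widening fallback trades
  calendar fidelity for availability.
* The exact conditional likelihood is implemented for 1 case : M
  referents (the case-crossover setting), not for general m:n matching.
* Delta-method intervals for RERI and AP are first-order; with few
  jointly exposed cases they can undercover, which is why suppression of
  sparse cells is on by default.
* ICD classification implements the published category ranges only; it
  is not a general ICD-9→ICD-10 equivalence mapping.
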