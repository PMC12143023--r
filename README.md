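# heatsmoke

Joint effects of extreme heat and wildfire smoke on hospitalizations:
a complete, tested implementation of a time-stratified case-crossover
interaction analysis, with a synthetic-data generator for validation
against known ground truth.

## Who this is for

Environmental epidemiologists and biostatisticians studying compound
climate hazards. Hospitalization records of the kind this design needs
are confidential, so the package pairs the analysis machinery with a
generator that emulates every input — gridded daily maximum temperature,
gridded PM2.5 with plume-driven spikes, satellite plume masks, a
population surface, a grid-to-ZCTA crosswalk, and case records whose
within-stratum admission-day probabilities follow the analysis model
with configurable coefficients.

## The model

Each case day is matched to the 3–4 other days in the same month and
year sharing its day of week. Within a stratum, the log-odds of
hospitalization are

    logit Pr(Y=1|X) = b0i + bH*X_HEAT + bS*X_SMOKE + bHS*X_HEAT*X_SMOKE

with `X_HEAT` a binary extreme-heat indicator (daily Tmax strictly above
its month- and ZCTA-specific 90th/95th/99th percentile) and `X_SMOKE`
continuous wildfire-influenced PM2.5 (total PM2.5 minus the expected
smoke-free concentration, on plume-overlapped exceedance days), each at
its own lag of 0–3 days. The stratum intercepts `b0i` cancel in the
exact conditional likelihood, which the package maximizes by
Newton–Raphson with analytic derivatives. From a fit at smoke increment
delta (default 1 µg/m³):

    OR01 = exp(bH)            OR10 = exp(bS*d)     OR11 = exp(bH + bS*d + bHS*d)
    multiplicative = OR11 / (OR01*OR10)
    RERI = OR11 - OR10 - OR01 + 1        (additive-scale interaction)
    AP   = RERI / OR11                   (attributable proportion)

RERI and AP carry delta-method confidence intervals propagated through
the fit covariance; positive values indicate super-additive joint
effects.

## Worked example

```r
library(heatsmoke)

cfg <- simulation_config(
  n_cases = 5000L,
  truth = simulation_truth(beta_H = 0.5, beta_S = 0.05, beta_HS = 0.15,
                           heat_lag = 0L, smoke_lag = 3L),
  seed = 42L)

env       <- generate_environment(cfg)
baseline  <- smoke_free_baseline(env$pm25, env$plumes)
wf        <- wf_influenced_pm25(env$pm25, env$plumes, baseline)
exposures <- build_exposure_series(env$tmax, wf, env$crosswalk)
exposures <- flag_extreme_heat(exposures, heat_thresholds(exposures), 95)

cases  <- simulate_cases(cfg, exposures, zip_to_zcta = env$zip_to_zcta)
design <- build_strata(cases, exposures, outcome = "all_natural",
                       heat_lag = 0L, smoke_lag = 3L, months = "all")
fit <- fit_clogit(design)
print(fit)
#> Conditional logistic interaction fit
#>         estimate      se       z       p
#> beta_H   0.63522 0.06641 9.56553 0.00000
#> beta_S   0.05909 0.02394 2.46794 0.01359
#> beta_HS  0.14693 0.07973 1.84291 0.06534
#> loglik -4644.8912 | 3187 strata (1755 non-informative dropped) | converged in 4 iterations

interaction_measures(fit, delta = 1)
#> Interaction measures (smoke increment delta = 1 ug/m3, 95% CI)
#>  OR01 (heat alone):    1.8874  [ 1.6571,  2.1498]  p=1.116e-21
#>  OR10 (smoke alone):   1.0609  [ 1.0122,  1.1118]  p=0.01359
#>  OR11 (joint):         2.3192  [ 1.9619,  2.7416]  p=6.543e-23
#>  multiplicative:       1.1583  [ 0.9907,  1.3542]  p=0.06534
#>  RERI:                 0.3709  [ 0.0334,  0.7085]  p=0.03126
#>  AP:                   0.1599  [ 0.0336,  0.2863]  p=0.01311
#>  p-values: two-sided normal ('_p1' one-sided)
```

The generator's truth was `beta_H = 0.5`, `beta_S = 0.05`,
`beta_HS = 0.15` acting at heat lag 0 and smoke lag 3; the fit at that
lag pair recovers all three within sampling error (5,000 cases). The AP
row says an estimated 16% (95% CI 3%–29%) of jointly-exposed
hospitalizations in this synthetic world are attributable to the
heat × smoke synergy.

The full study — all 16 lag pairs per outcome, subgroup stratification,
suppression of cells with fewer than 10 exposed cases, CSV/JSON reports
— runs through `run_lag_grid()`, `run_stratified()` and
`write_report()`, or from a shell via the thin CLI in
`inst/cli/heatsmoke` (`simulate`, `build-exposures`, `run`, `report`
subcommands, one YAML/JSON config).

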