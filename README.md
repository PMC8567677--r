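# heatvuln

Two-stage heat-vulnerability analysis: county-level heat–morbidity odds
ratios from a time-stratified case-crossover design, then regression of
those odds ratios on county demographic and socioeconomic variables with
spatial diagnostics.

## Who this is for

Environmental epidemiologists and public-health analysts who have (or can
simulate) three inputs — individual acute-care visit records, daily
county-scale weather, and an area-level covariate table — and want to know
*where* heat-related risk is highest and *which* social determinants of
health (SDOH) track it, outcome by outcome.

## The method

**Stage 1.** For each county, outcome (cardiovascular, dehydration,
heat-related, acute renal, respiratory disease; ICD-9 classified), and
stream (ED visit vs hospital admission), a case-crossover design compares
heat exposure on each visit day with exposure on three referent days for
the same person. Referents come from a fixed 28-day comparison window:
seasons are partitioned into 28-day blocks and a case is matched to the
other same-weekday days of its block, i.e. offsets drawn from ±7, ±14,
±21 days, before and after the event — so seasonality and day-of-week
cycles cancel and controls are exactly 3× cases. The county odds ratio per
°C is exp(β̂) from the conditional logistic likelihood

    l(beta) = sum_s [ beta * x_case,s  -  log sum_{j in s} exp(beta * x_j,s) ]

maximised by Newton–Raphson (implemented in the package, no regression
dependency). Exposure metrics: daily max/mean/min temperature and daily
maximum Heat Index (Rothfusz polynomial with the standard NWS
adjustments), lags 0–10 days, selectable by pooled AIC. Repeat visits
within 7 days (dehydration, heat-related, respiratory) or 28 days
(cardiovascular, acute renal) are deduplicated; counties under 30 cases
are excluded.

**Stage 2.** County odds ratios are regressed on SDOH covariates: pairwise
correlation pruning at |r| > 0.7, backward stepwise AIC selection, then
either an aspatial linear model or a maximum-likelihood spatial lag model
`y = rho W y + X beta + eps` on binary queen-contiguity weights — the
spatial model is chosen when aspatial residuals show Moran's I
autocorrelation (Monte Carlo p ≤ 0.05) or it has lower AIC. Spatial-model
effects are reported as global average total impacts.

A seeded synthetic-data generator (`sim_config()`, `simulate_inputs()`)
emulates warm-season weather with seasonal cycle and autocorrelation,
correlated SDOH, lattice adjacency, and Poisson events whose county log-OR
per °C is a known linear function of SDOH — so the whole pipeline is
testable with known ground truth and no restricted data.

## Worked example

```r
library(heatvuln)

cfg <- run_config(
  out_dir = "demo_run",
  sim = sim_config(n_counties = 49, n_rows = 7, n_cols = 7,
                   years = 2008:2010, baseline_rate = 3, seed = 42),
  n_permutations = 499, seed = 42
)
res <- run_pipeline(cfg)
head(res$county_ors[c("county_id", "or_value", "se", "n_cases", "aic")], 4)
#>   county_id or_value      se n_cases  aic
#> 1      C001   1.0238 0.01839    1263 3502
#> 2      C002   1.0579 0.01918    1285 3556
#> 3      C003   0.9478 0.01915    1248 3454
#> 4      C004   1.0265 0.02073    1219 3380

print(res$stage2$results[[1]])
#> <stage2_model> MLR  AIC=-238.70 (MLR -238.70 / spatial -237.87)
#>   Moran's I on MLR residuals: 0.0079 (mc p=0.668); KS p=0.534
#>                               estimate           se            p
#> pct_under_5                0.004063366 0.0024647150 1.065149e-01
#> pct_over_65                0.002361241 0.0003907694 3.170858e-07
#> unemployment_rate         -0.001861106 0.0013329871 1.698234e-01
#> pct_farm_fish_mine_forest -0.002049964 0.0007799174 1.184687e-02
#> pct_install_maint_repair  -0.006341760 0.0026560848 2.142283e-02
```

Reading the output: county C002's odds of a dehydration ED visit rise by
5.8% per 1 °C of concurrent-day mean temperature (OR 1.058). Across the 49
counties, a one-point increase in percent over 65 raises the county OR by
about 0.0024 (the generator planted 0.002 on that variable, and −0.003 on
the unemployment rate, estimated −0.0019 here); residuals show no spatial
autocorrelation (Moran p = 0.67), so the aspatial model is kept. The run
writes every intermediate artifact (`events_raw.csv`, `exposure.csv`,
`county_or.csv`, `stage2.csv`, `report.json`, ...) under `out_dir`; the
JSON report carries record counts at every filter (events read,
deduplicated, strata built and dropped, counties fitted or excluded).

A thin command-line wrapper with `simulate` / `exposure` / `casecrossover`
/ `spatial` / `all` subcommands ships in `inst/cli/heatvuln.R`.

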