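---
title: "Methods: two-stage heat vulnerability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage heat vulnerability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatvuln)
```

## The two-stage model

`heatvuln` quantifies how warm-season heat affects acute morbidity and how
that effect varies with county-level social determinants of health (SDOH),
in two stages.

**Stage 1 (within counties, over time).** For each county, outcome class
(cardiovascular, dehydration, heat-related, acute renal, respiratory), and
care stream (emergency department vs hospital admission), a case-crossover
design compares the heat exposure on the day of each visit (the case day)
with the exposure on referent days when the same person did not seek care.
Because each person is their own control, all time-invariant confounders
(age, sex, chronic conditions, ...) cancel by design. With one scalar
exposure $x$ (degrees Celsius) the conditional logistic likelihood over
matched sets $s$ is

$$\ell(\beta) = \sum_s \left[\beta x_{\text{case},s} -
  \log \sum_{j \in s} e^{\beta x_{j,s}}\right],$$

and $e^{\hat\beta}$ is the county's odds ratio (OR) per 1 °C. Exposure
metrics are daily maximum, mean, and minimum temperature and the daily
maximum Heat Index, at lags 0–10 days; the concurrent-day mean temperature
is the default, and `select_best_metric_lag()` can choose the combination
with the lowest AIC pooled over counties (on a common set of strata, so the
AICs are comparable across the grid).

**Stage 2 (across counties, over space).** The county ORs (counties with at
least 30 retained cases) become the response in a regression on county SDOH
covariates: candidates are first pruned so no surviving pair has absolute
Pearson correlation above 0.7, then backward stepwise AIC deletion selects
a final set, and the model is either an aspatial linear regression or a
maximum-likelihood spatial lag model

$$y = \rho W y + X\beta + \varepsilon,$$

with $W$ a binary (not row-standardised) first-order queen contiguity
matrix. The spatial model is used whenever the aspatial residuals show
spatial autocorrelation (Moran's I Monte Carlo $p \le 0.05$) or the spatial
model has strictly lower AIC. Under the spatial model, reported per-variable
effects are global average total impacts,
$n^{-1}\mathbf{1}^\top (I-\rho W)^{-1} \mathbf{1}\,\beta_k$, which fold in
spillover through neighbours.

## Referent selection: why fixed calendar strata

The design draws three referents per case from the ±7, ±14, ±21 day offsets
of a 28-day comparison window, so referents share the case's day of week
and fall both before and after the event. There are two ways to realise
this rule:

1. **Case-anchored**: centre the window on the case day and pick one side
   of each offset at random, falling back to the other side near the season
   boundary.
2. **Time-stratified**: partition each season into fixed 28-day blocks
   anchored at the season start and use the other three same-weekday days
   of the case's block.

We implement the second. The case-anchored variant makes the matched set a
function of the case day, so set membership is not exchangeable: with any
smooth seasonal exposure trend, referents near the boundary are forced
toward one (systematically warmer or cooler) side, and even mid-season the
curvature of the seasonal cycle leaves referents cooler on average than
cases. In simulations with a planted log-OR of 0.05/°C this produced
estimates around 0.013 (boundary fallback included) or 0.090 (boundary
cases excluded) — severe bias in both directions. With fixed calendar
strata every day of a block carries the same referent set, the conditional
likelihood is exchangeable, and the same simulations recover the planted
effect without bias (`stage1_recovery` checks in the test suite).

Consequences of the fixed-stratum choice:

- every case in a complete block has exactly 3 referents, so controls are
  exactly 3x cases — the design's structural ratio;
- referent offsets are a 3-subset of {±7, ±14, ±21} days (e.g. a case in
  week 2 of its block has referents at −14, −7, +7 days);
- seasons whose length is not a multiple of 28 days end with an incomplete
  block (days 141–153 of a May–September season); cases there lack three
  same-weekday stratum mates and are dropped with a logged count (~8% of
  season days). We prefer this explicit, counted loss to a biased estimate;
- selection is deterministic, so results are reproducible and invariant to
  event row order with no referent RNG at all.

## Deduplication

Repeat visits by the same person within an outcome-specific episode window
(7 days for dehydration, heat-related, and respiratory illness; 28 days for
cardiovascular and acute renal disease) are treated as the same illness
episode: scanning each patient–outcome stream chronologically, a visit
closer than the window to the last *retained* visit is dropped. The scan is
idempotent, and the first visit is always kept.

## The synthetic-data generator

Real inputs of this analysis (individual health events, assimilation-model
weather, census SDOH tables) are restricted or bulky, so the package ships
a generator whose defaults emulate the study conditions — 67 counties on a
lattice, May 1 – September 30 seasons of 2008–2012 — with known ground
truth:

- **Weather**: county daily mean temperature = within-season sinusoid
  (baseline 24 °C, amplitude 4 °C, peaking mid-season) + a time-invariant
  county offset (SD 1 °C) + AR(1) anomalies (coefficient 0.7, innovation SD
  1.2 °C, restarted each season); daily max/min bracket the mean by half a
  7 °C diurnal range plus day-to-day fluctuation (SD 1 °C), so the four
  exposure metrics are correlated but distinguishable; relative humidity is
  a clipped noisy 70% baseline. These magnitudes are typical of a humid
  subtropical warm season.
- **SDOH**: a multivariate normal over eight roster variables with
  county-level means and SDs on realistic scales, including one income pair
  planted at correlation 0.95 (so pruning always has work to do) and other
  correlations at most 0.35.
- **Adjacency**: first-order queen contiguity of the county lattice.
- **Events**: the county log-OR per °C is planted as
  $\beta_c = \gamma_0 + \sum_v \gamma_v\,x_{cv} + u_c + e_c$, with optional
  spatially autocorrelated noise $u$ (white noise filtered through
  $(I-\rho_s W_{\text{row}})^{-1}$) and independent noise $e$. Daily counts
  are Poisson with mean
  $\lambda_{cd} = \text{rate} \cdot e^{\beta_c (T_{cd} - \bar T_c)}$, so
  the case-crossover OR per °C equals $e^{\beta_c}$ by construction —
  log-linearity is our modelling choice, made because it gives the analysis
  a well-defined truth. Default effects are planted on `pct_over_65`
  (+0.002) and `unemployment_rate` (−0.003): deliberately *not* on a member
  of the collinear income pair, because an effect carried by a variable the
  pruning step may remove would make truth recovery ill-posed. A fraction
  of patients (default 10%) receives a duplicate visit 1 to (window−1)
  days later to exercise deduplication.

What the generator does **not** emulate: real county geographies and
populations, realistic ICD-9 code frequencies, weekday/holiday cycles in
care seeking, humidity–temperature dependence, multi-outcome case mix, or
measurement error in SDOH. Passing tests therefore demonstrate correctness
of the estimators under the stated generative model; substantive
conclusions about any real region require the restricted source data.

## Numerical choices

- **Conditional logistic fit**: Newton–Raphson from $\beta = 0$ on
  stratum-centred exposures with log-sum-exp stabilisation; convergence
  when the Newton step is below 1e−10 (a scale-free criterion; the raw
  score is $n$-scaled), at most 50 iterations; monotone escape beyond
  $|\beta| = 10$ is reported as non-convergence with $\beta$ capped (this
  happens iff the case exposure is the stratum maximum/minimum in every
  stratum). Strata with no exposure contrast contribute nothing; if all are
  degenerate the fit returns $\beta = 0$ with infinite standard error and a
  flag. AIC is $2 - 2\ell(\hat\beta)$.
- **Heat Index**: the nine-coefficient regression polynomial in °F, with
  the standard low-humidity subtraction (RH < 13%, 80–112 °F) and
  high-humidity addition (RH > 85%, 80–87 °F), and the simple-formula
  average below 80 °F. Each adjustment is flag-controlled so the bare
  polynomial is testable. The 80 °F handoff is intrinsically discontinuous;
  the measured jump is below 2 °F up to RH ≈ 65% and peaks near 2.8 °F at
  RH 80%. Internally everything is Celsius (ORs are per °C); the index is
  evaluated in °F and converted.
- **Spatial lag ML**: the concentrated log-likelihood
  $\sum_i \log(1-\rho\lambda_i) - (n/2)\log(\text{SSE}(\rho)/n)$ is
  maximised over the feasible interval $(1/\lambda_{\min},
  1/\lambda_{\max})$ by bounded scalar search (tolerance 1e−10), with the
  log-determinant from the precomputed eigenvalues of $W$; an optimum
  within 1e−4 of an endpoint is flagged non-converged. Standard errors come
  from the inverse information matrix in $(\beta, \rho, \sigma^2)$. A zero
  weights matrix leaves $\rho$ unidentified: the fit collapses exactly to
  OLS with $\rho = 0$ and a flag.
- **Moran's I**: binary weights as given (no row standardisation);
  permutation p-values are two-sided by doubling the smaller tail of
  $(1 + \#\{I^* \text{ at least as extreme}\})/(1 + B)$, default
  $B = 999$.
- **Pruning ties**: the member of the worst pair with the larger mean
  absolute correlation against the other remaining variables is dropped;
  exact ties drop the later column. An explicit drop list overrides the
  greedy rule for reproducing a published removal set.
- **Missing weather days** are a hard error, never interpolated: silent
  gap-filling would distort referent contrasts.

## Open design choices

- **OR vs log-OR response.** Stage 2 regresses the OR itself by default,
  matching the framing of ORs as the dependent variable; `use_log_or =
  TRUE` switches to the log scale, which is what the parameter-recovery
  tests use because the planted truth is a log-OR.
- **Stepwise under which fitter.** Variable selection runs under the
  aspatial fitter by default and the chosen model is then refitted on the
  selected set; `stepwise_spatial = TRUE` runs the search under the
  spatial-lag fitter instead.
- **Impact p-values** are carried from the coefficient tests; no
  simulation-based impact inference is attempted, since the spatial term is
  a nuisance control here rather than a target of inference.
- **No precision weighting** of county ORs by their stage-1 standard
  errors; the second stage is an unweighted regression. Counties with more
  cases have more precise ORs, so this leaves some heteroscedasticity on
  the table — a known limitation.
- **No multiple-testing correction**; significance is flagged at
  $p \le 0.05$ per model.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the estimators at sizes
chosen to make their statistical properties visible while staying
desk-scale: null calibration of the county Wald test uses 500 counties with
~280 retained cases each; stage-1 recovery uses 100 replicates of a single
county with ~5,000 cases; stage-2 recovery uses 50 replicates of 100
counties with ~2,000 cases per county, run through the full prune →
stepwise → model-choice pipeline; spatial-lag recovery plants
$\rho = 0.1$ on a 7×7 queen lattice (safely inside the feasible interval
of the binary weights); Moran calibration uses 200 null replicates with 199
permutations each.

## Limitations

County-level associations are ecologic: they need not hold for
individuals, and results are contingent on the areal unit. The referent
design trades ~8% of cases (incomplete trailing stratum) for unbiasedness.
The spatial lag model controls residual autocorrelation but is not a
structural model of spatial diffusion, and alternative spatial families
(spatial error, SARAR, GWR) are out of scope, as are nonlinear
(spline/distributed-lag) exposure–response shapes, mortality outcomes, and
ICD-10 coding.
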