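test_that("ICD-9 codes classify into the five outcome ranges", {
  expect_equal(classify_outcome("276.51"), "dehydration")
  expect_equal(classify_outcome("584.6"), "acute_renal")
  expect_equal(classify_outcome("250.00"), NA_character_)
  expect_equal(
    classify_outcome(c("390", "459.81", "460", "519.9", "992.0", "E900.1")),
    c("cardiovascular", "cardiovascular", "respiratory", "respiratory",
      "heat_related", "heat_related")
  )
  # boundary exclusions: 276.5 without the .51 is not dehydration; 584.4
  # falls outside the acute renal band
  expect_equal(classify_outcome(c("276.5", "584.4", "E900.2")),
               rep(NA_character_, 3))
  expect_warning(out <- classify_outcome("not-a-code"), "unparseable")
  expect_equal(out, NA_character_)
})

test_that("deduplication drops repeat visits inside the episode window", {
  mk <- function(days, outcome) data.frame(
    patient_id = 1L, date = as.Date("2009-06-01") + days,
    outcome = outcome, stringsAsFactors = FALSE
  )
  # dehydration, 7-day window: day 5 dropped, day 8 kept
  expect_equal(nrow(deduplicate_events(mk(c(0, 5), "dehydration"))), 1)
  expect_equal(nrow(deduplicate_events(mk(c(0, 8), "dehydration"))), 2)
  # cardiovascular, 28-day window, scan keyed to the last *retained* visit:
  # days 0, 20, 40 -> keep 0 and 40
  got <- deduplicate_events(mk(c(0, 20, 40), "cardiovascular"))
  expect_equal(as.numeric(got$date - as.Date("2009-06-01")), c(0, 40))
  # idempotence
  expect_equal(nrow(deduplicate_events(got)), nrow(got))
  # different patients never interact
  two <- rbind(mk(0, "dehydration"),
               transform(mk(2, "dehydration"), patient_id = 2L))
  expect_equal(nrow(deduplicate_events(two)), 2)
  expect_error(deduplicate_events(mk(0, "sprained_ankle")), "window")
})

test_that("referent sets have the time-stratified 28-day structure", {
  # early-season case: all three referents after the event
  refs <- select_referents(as.Date("2009-05-03"))
  expect_equal(as.Date(refs[1, ], origin = "1970-01-01"),
               as.Date(c("2009-05-10", "2009-05-17", "2009-05-24")))

  # mid-season case: 3 referents, each offset magnitude in {7, 14, 21},
  # bidirectional
  refs2 <- select_referents(as.Date("2010-07-15"))
  d <- as.numeric(refs2[1, ]) - as.numeric(as.Date("2010-07-15"))
  expect_equal(sort(abs(d)) %in% c(7, 14, 21), rep(TRUE, 3))
  expect_true(any(d < 0) && any(d > 0))

  # exchangeability: the stratum of a case day contains its referents, and
  # each referent's own referent set contains the case day
  for (r in as.Date(refs2[1, ], origin = "1970-01-01")) {
    back <- select_referents(as.Date(r, origin = "1970-01-01"))
    expect_true(as.numeric(as.Date("2010-07-15")) %in% back[1, ])
  }

  # deterministic on rerun
  dates <- season_dates(2009)[1:140]
  expect_identical(select_referents(dates), select_referents(dates))

  # cases in the trailing incomplete stratum are flagged
  late <- select_referents(as.Date("2009-09-29"))
  expect_true(all(is.na(late)))

  # every complete-stratum case gets exactly 3 in-season referents
  refs_all <- select_referents(dates)
  expect_true(all(!is.na(refs_all)))
  expect_true(all(format(as.Date(as.numeric(refs_all), origin = "1970-01-01"),
                         "%m-%d") >= "05-01"))
  expect_error(select_referents(as.Date("2009-02-01")), "warm season")
})

test_that("strata carry 4 exposure values and honour the missing-data rule", {
  wx <- make_weather_fixture(n_counties = 1, years = 2009)
  expo <- build_exposure(wx)
  dates <- as.Date("2009-06-10") + 0:19
  events <- data.frame(
    patient_id = seq_along(dates), date = dates, outcome = "dehydration",
    stream = "ED", county_id = "C001", stringsAsFactors = FALSE
  )
  st <- build_strata(events, expo, "tmean", lag = 0)
  expect_equal(nrow(st$x), 20)
  expect_equal(ncol(st$x), 4)
  expect_false(anyNA(st$x))

  # referent count is exactly 3x the stratum count
  expect_equal(3 * nrow(st$x), 60)

  # a case whose stratum reaches before the season start at lag 7 is dropped
  early <- data.frame(patient_id = 1L, date = as.Date("2009-05-08"),
                      outcome = "dehydration", stream = "ED",
                      county_id = "C001", stringsAsFactors = FALSE)
  st7 <- build_strata(early, expo, "tmean", lag = 7)
  expect_equal(nrow(st7$x), 0)
  expect_equal(st7$n_dropped_exposure, 1)
  expect_error(build_strata(events, expo, "dewpoint", 0), "arg")
})

test_that("conditional logistic fit matches independent oracles", {
  # no contrast -> degenerate zero fit
  flat <- matrix(25, 10, 4)
  f0 <- conditional_logistic_fit(flat)
  expect_equal(f0$beta, 0)
  expect_equal(f0$or_value, 1)
  expect_true(f0$degenerate)
  expect_equal(f0$se, Inf)

  # per-stratum constant shifts leave the estimate unchanged
  x <- make_strata(30, beta = 0.5, seed = 7)
  f1 <- conditional_logistic_fit(x)
  f2 <- conditional_logistic_fit(x + rnorm(30))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)

  # dense grid maximisation of the independently coded likelihood
  expect_equal(f1$beta, oracle_clogit_grid(x), tolerance = 1e-4)
  expect_true(f1$converged)

  # likelihood at the optimum dominates every grid point
  grid <- seq(-2, 2, length.out = 400)
  ll_grid <- vapply(grid, oracle_clogit_loglik, 0, x = x)
  expect_gte(f1$loglik + 1e-10, max(ll_grid))
  expect_gte(f1$loglik, oracle_clogit_loglik(0, x))

  # 1:1 matched pairs with binary exposure: beta-hat = log(n10/n01)
  n10 <- 17; n01 <- 9
  pairs <- rbind(
    matrix(rep(c(1, 0), n10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), n01), ncol = 2, byrow = TRUE)
  )
  fp <- conditional_logistic_fit(pairs)
  expect_equal(fp$beta, log(n10 / n01), tolerance = 1e-6)

  # independent implementation cross-check (survival::clogit)
  suppressPackageStartupMessages(library(survival))
  long <- data.frame(
    y = rep(c(1, 0, 0, 0), 30),
    xv = as.vector(t(x)),
    id = rep(1:30, each = 4)
  )
  cl <- clogit(y ~ xv + strata(id), data = long)
  expect_equal(f1$beta, unname(coef(cl)), tolerance = 1e-6)
  expect_equal(f1$se, sqrt(unname(diag(vcov(cl)))), tolerance = 1e-6)
  expect_equal(f1$aic, AIC(cl), tolerance = 1e-6)

  # case always the stratum maximum -> monotone likelihood, flagged
  xmax <- t(replicate(10, sort(rnorm(4), decreasing = TRUE)))
  fm <- conditional_logistic_fit(xmax)
  expect_false(fm$converged)
  expect_equal(abs(fm$beta), 10)
})

test_that("county estimates respect the 30-case inclusion rule", {
  wx <- make_weather_fixture(n_counties = 2, years = 2009)
  expo <- build_exposure(wx)
  dates29 <- as.Date("2009-06-01") + seq_len(29)
  dates30 <- as.Date("2009-06-01") + seq_len(30)
  events <- rbind(
    data.frame(patient_id = seq_along(dates29), date = dates29,
               outcome = "dehydration", stream = "ED", county_id = "C001",
               stringsAsFactors = FALSE),
    data.frame(patient_id = 100L + seq_along(dates30), date = dates30,
               outcome = "dehydration", stream = "ED", county_id = "C002",
               stringsAsFactors = FALSE)
  )
  ors <- estimate_county_ors(events, expo, "tmean", 0, min_cases = 30)
  expect_equal(ors$county_id, "C002")
  expect_equal(ors$n_cases, 30)
  excl <- attr(ors, "excluded")
  expect_equal(excl$county_id, "C001")
  expect_equal(excl$n_cases, 29)
})

test_that("estimates are invariant to event row order", {
  cfg <- sim_config(n_counties = 4, n_rows = 2, n_cols = 2, years = 2009,
                    baseline_rate = 2, dup_frac = 0, seed = 31)
  sim <- simulate_inputs(cfg)
  expo <- build_exposure(sim$weather)
  ors1 <- estimate_county_ors(sim$events, expo, "tmean", 0, min_cases = 10)
  set.seed(1)
  shuffled <- sim$events[sample(nrow(sim$events)), ]
  ors2 <- estimate_county_ors(shuffled, expo, "tmean", 0, min_cases = 10)
  expect_equal(ors1, ors2, ignore_attr = TRUE)
})

test_that("pooled AIC selects the generating metric and lag", {
  cfg <- sim_config(n_counties = 1, n_rows = 1, n_cols = 1, years = 2008:2009,
                    baseline_rate = 8, gamma = c(), gamma0 = 0.08,
                    beta_noise_sd = 0, dup_frac = 0, seed = 41)
  wx <- generate_weather(cfg)
  ev <- generate_events(cfg, wx, data.frame(county_id = "C001"))
  expo <- build_exposure(wx)
  sel <- select_best_metric_lag(ev$events, expo, lags = 0:2)
  expect_equal(sel$metric, "tmean")
  expect_equal(sel$lag, 0)
  expect_equal(nrow(sel$aic_table), 4 * 3)
  # all cells fitted on the same strata, so AICs are comparable
  expect_equal(length(unique(sel$aic_table$n_strata)), 1)

  single <- select_best_metric_lag(ev$events, expo, metrics = "tmax",
                                   lags = 5)
  expect_equal(single$metric, "tmax")
  expect_equal(single$lag, 5)
  expect_equal(nrow(single$aic_table), 1)
})
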