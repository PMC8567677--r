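#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' a state-scale warm-season morbidity analysis in a humid subtropical
#' climate: 67 counties, warm seasons (May 1 - September 30) of 2008-2012, and a
#' county log-odds-ratio per degree Celsius that is a known linear function
#' of the generated demographic/socioeconomic covariates plus optional
#' spatially autocorrelated noise.
#'
#' @param n_counties number of counties (arranged on an `n_rows x n_cols`
#'   lattice for adjacency; defaults to 67).
#' @param n_rows,n_cols lattice dimensions; must multiply to `n_counties`.
#' @param years study years (default 2008:2012).
#' @param season season start/end as "MM-DD" (default May 1 - Sep 30).
#' @param baseline_rate expected events per county per day at average
#'   temperature (> 0).
#' @param gamma named vector of true covariate effects on the county log-OR
#'   per degree Celsius (per covariate unit); names must be generated SDOH
#'   columns.
#' @param gamma0 intercept of the county log-OR model (log-OR per deg C).
#' @param beta_noise_sd SD of independent county-level log-OR noise (>= 0).
#' @param spatial_rho autoregressive parameter in \[0, 1) of the planted
#'   spatially correlated log-OR noise (simultaneous-autoregressive filter on
#'   the row-normalised queen lattice weights).
#' @param spatial_sd SD of the innovations entering the spatial filter.
#' @param dup_frac fraction of events that receive a planted duplicate visit
#'   inside the deduplication window (to exercise deduplication).
#' @param outcome,stream outcome class and care stream the simulated events
#'   carry.
#' @param t_base,t_amp seasonal sinusoid baseline and amplitude (deg C).
#' @param county_offset_sd SD of time-invariant county temperature offsets.
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD of daily
#'   temperature anomalies.
#' @param dtr typical diurnal temperature range: tmax - tmin (deg C).
#' @param dtr_sd SD of the day-to-day half-range fluctuations (deg C); with
#'   0 the range is constant and tmax/tmin are deterministic offsets of
#'   tmean.
#' @param seed RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_counties = 67,
                       n_rows = NULL, n_cols = NULL,
                       years = 2008:2012,
                       season = c("05-01", "09-30"),
                       baseline_rate = 2,
                       gamma = c(pct_over_65 = 0.002, unemployment_rate = -0.003),
                       gamma0 = 0.03,
                       beta_noise_sd = 0.005,
                       spatial_rho = 0,
                       spatial_sd = 0.005,
                       dup_frac = 0.1,
                       outcome = "dehydration",
                       stream = "ED",
                       t_base = 24, t_amp = 4,
                       county_offset_sd = 1, ar_phi = 0.7, ar_sd = 1.2,
                       dtr = 7, dtr_sd = 1,
                       seed = 1L) {
  if (is.null(n_rows)) {
    n_rows <- max(1L, floor(sqrt(n_counties)))
    while (n_counties %% n_rows != 0) n_rows <- n_rows - 1L
  }
  if (is.null(n_cols)) n_cols <- n_counties %/% n_rows
  cfg <- list(
    n_counties = as.integer(n_counties), n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols), years = as.integer(years), season = season,
    baseline_rate = baseline_rate, gamma = gamma, gamma0 = gamma0,
    beta_noise_sd = beta_noise_sd, spatial_rho = spatial_rho,
    spatial_sd = spatial_sd, dup_frac = dup_frac,
    outcome = outcome, stream = stream,
    t_base = t_base, t_amp = t_amp, county_offset_sd = county_offset_sd,
    ar_phi = ar_phi, ar_sd = ar_sd, dtr = dtr, dtr_sd = dtr_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_counties < 1) stop("n_counties must be positive")
  if (cfg$n_rows * cfg$n_cols != cfg$n_counties) {
    stop("n_rows * n_cols must equal n_counties")
  }
  if (length(cfg$years) == 0) stop("`years` must not be empty")
  ss <- as.Date(paste0("2001-", cfg$season[1]))
  se <- as.Date(paste0("2001-", cfg$season[2]))
  if (se <= ss) stop("season end must fall after season start")
  if (cfg$baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (cfg$beta_noise_sd < 0 || cfg$spatial_sd < 0 || cfg$ar_sd < 0 ||
      cfg$county_offset_sd < 0 || cfg$dtr_sd < 0) {
    stop("rates and standard deviations must be non-negative")
  }
  if (cfg$spatial_rho < 0 || cfg$spatial_rho >= 1) {
    stop("spatial_rho must lie in [0, 1)")
  }
  if (cfg$dup_frac < 0 || cfg$dup_frac > 1) stop("dup_frac must lie in [0, 1]")
  if (!cfg$outcome %in% names(OUTCOME_DEDUP_WINDOWS)) {
    stop("unknown outcome: ", cfg$outcome)
  }
  invisible(cfg)
}

#' Generate warm-season daily county weather
#'
#' Daily mean temperature per county is a within-season sinusoid (peaking
#' mid-season) plus a time-invariant county offset plus AR(1) anomalies
#' restarted each season. Daily max/min bracket the mean by half the diurnal
#' range; relative humidity is a clipped noisy baseline in \[5, 100\].
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `county_id`, `date`, `tmax_c`, `tmean_c`,
#'   `tmin_c`, `rh_pct`; one row per county per in-season day.
#' @export
generate_weather <- function(config) {
  validate_sim_config(config)
  dates <- season_dates(config$years, config$season)
  n_days <- length(dates)
  ids <- county_ids(config$n_counties)
  bounds <- season_bounds(dates, config$season)
  frac <- as.numeric(dates - bounds$start) /
    as.numeric(bounds$end - bounds$start)
  clim <- config$t_base + config$t_amp * sin(pi * frac)

  set.seed(stage_seed(config$seed, "weather"))
  offsets <- rnorm(config$n_counties, 0, config$county_offset_sd)
  yr <- as.integer(format(dates, "%Y"))
  out <- vector("list", config$n_counties)
  for (c_i in seq_len(config$n_counties)) {
    anom <- numeric(n_days)
    innov <- rnorm(n_days, 0, config$ar_sd)
    for (s in split(seq_len(n_days), yr)) {
      prev <- 0
      for (i in s) {
        prev <- config$ar_phi * prev + innov[i]
        anom[i] <- prev
      }
    }
    tmean <- clim + offsets[c_i] + anom
    rh <- pmin(100, pmax(5, 70 + rnorm(n_days, 0, 8)))
    up <- config$dtr / 2 + abs(rnorm(n_days, 0, config$dtr_sd))
    down <- config$dtr / 2 + abs(rnorm(n_days, 0, config$dtr_sd))
    out[[c_i]] <- data.frame(
      county_id = ids[c_i], date = dates,
      tmax_c = tmean + up, tmean_c = tmean,
      tmin_c = tmean - down, rh_pct = rh
    )
  }
  do.call(rbind, out)
}

# Default synthetic SDOH marginals (county-level means/SDs on realistic
# scales) and correlation structure. The per-capita / household income pair
# is planted far above the 0.7 pruning threshold.
default_sdoh_spec <- function() {
  vars <- c(
    "pct_under_5", "pct_over_65", "pct_female", "unemployment_rate",
    "pct_farm_fish_mine_forest", "pct_install_maint_repair",
    "per_capita_income", "median_household_income"
  )
  mu <- c(5.6, 18.3, 48.7, 12.6, 2.5, 4.1, 23.1, 44.3)
  sdv <- c(1.0, 6.8, 3.7, 2.5, 4.5, 1.1, 5.9, 7.5)
  r <- diag(8)
  dimnames(r) <- list(vars, vars)
  r["per_capita_income", "median_household_income"] <- 0.95
  r["median_household_income", "per_capita_income"] <- 0.95
  r["pct_over_65", "per_capita_income"] <- r["per_capita_income", "pct_over_65"] <- 0.3
  r["pct_over_65", "median_household_income"] <- r["median_household_income", "pct_over_65"] <- 0.3
  r["unemployment_rate", "per_capita_income"] <- r["per_capita_income", "unemployment_rate"] <- -0.35
  r["unemployment_rate", "median_household_income"] <- r["median_household_income", "unemployment_rate"] <- -0.35
  r["pct_farm_fish_mine_forest", "pct_under_5"] <- r["pct_under_5", "pct_farm_fish_mine_forest"] <- 0.2
  list(variables = vars, mean = mu, sd = sdv, correlation = r)
}

#' Generate a correlated county SDOH table
#'
#' Draws county covariates from a multivariate normal with a specified
#' correlation matrix. The default structure plants one income pair with
#' correlation 0.95 (above the 0.7 pruning threshold) and leaves other pairs
#' modest, so correlation pruning is exercised. Percent-scaled variables are
#' clipped to \[0, 100\] and dollar-scaled ones floored at 1.
#'
#' @param config a [sim_config()] (uses `n_counties` and `seed`).
#' @param spec list with `variables`, `mean`, `sd`, `correlation` (defaults
#'   to [default_sdoh_spec()] internals).
#' @return data.frame with `county_id` plus one numeric column per covariate.
#' @export
generate_sdoh <- function(config, spec = default_sdoh_spec()) {
  validate_sim_config(config)
  if (config$n_counties < 2) stop("need at least 2 counties")
  if (length(spec$variables) < 2) stop("need at least 2 covariates")
  r <- spec$correlation
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  sigma <- diag(spec$sd) %*% r %*% diag(spec$sd)
  set.seed(stage_seed(config$seed, "sdoh"))
  x <- MASS::mvrnorm(config$n_counties, mu = spec$mean, Sigma = sigma)
  colnames(x) <- spec$variables
  pctcols <- grepl("^pct_|_rate$", spec$variables)
  x[, pctcols] <- pmin(100, pmax(0, x[, pctcols]))
  x[, !pctcols] <- pmax(1, x[, !pctcols])
  data.frame(county_id = county_ids(config$n_counties), x,
             stringsAsFactors = FALSE)
}

#' Queen-contiguity adjacency of a rectangular lattice
#'
#' Binary symmetric first-order queen contiguity for counties arranged on a
#' lattice in row-major order: neighbours share an edge or a corner, so
#' interior cells have 8 neighbours, edges 5, corners 3.
#'
#' @param n_rows,n_cols positive lattice dimensions.
#' @return `n x n` binary matrix (n = n_rows * n_cols) with county ids as
#'   dimnames, zero diagonal.
#' @export
generate_adjacency <- function(n_rows, n_cols) {
  if (n_rows < 1 || n_cols < 1) stop("lattice dimensions must be positive")
  n <- n_rows * n_cols
  row_i <- (seq_len(n) - 1) %/% n_cols
  col_i <- (seq_len(n) - 1) %% n_cols
  w <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    adj <- abs(row_i - row_i[i]) <= 1 & abs(col_i - col_i[i]) <= 1
    adj[i] <- FALSE
    w[i, adj] <- 1L
  }
  dimnames(w) <- list(county_ids(n), county_ids(n))
  w
}

# Representative ICD-9 code emitted per outcome class.
OUTCOME_ICD9 <- c(
  cardiovascular = "410.9", dehydration = "276.51", heat_related = "992.0",
  acute_renal = "584.9", respiratory = "491.9"
)

#' Generate health events with known ground truth
#'
#' Plants a county log-odds-ratio per degree Celsius
#' `beta_c = gamma0 + sum_v gamma_v * sdoh_cv + spatial noise + iid noise`,
#' where the spatial term filters white noise through
#' `(I - spatial_rho * W_row)^(-1)` on the row-normalised queen lattice.
#' Daily event counts are Poisson with mean
#' `baseline_rate * exp(beta_c * (tmean - county mean tmean))`, so the
#' case-crossover odds ratio per degree Celsius equals `exp(beta_c)` by
#' construction. Each event becomes one row with a masked integer patient id;
#' a fraction `dup_frac` of patients receive a duplicate visit 1 to
#' (window - 1) days later to exercise deduplication.
#'
#' @param config a [sim_config()].
#' @param weather daily weather from [generate_weather()].
#' @param sdoh covariate table from [generate_sdoh()].
#' @param adjacency queen adjacency from [generate_adjacency()]; required
#'   only when `spatial_rho > 0`.
#' @return list with `events` (data.frame: `patient_id`, `date`, `icd9`,
#'   `outcome`, `stream`, `county_id`, `zip_id`) and `truth` (list:
#'   `county_beta`, `gamma`, `gamma0`, `sdoh_table`).
#' @export
generate_events <- function(config, weather, sdoh, adjacency = NULL) {
  validate_sim_config(config)
  ids <- county_ids(config$n_counties)
  if (!all(ids %in% weather$county_id)) stop("weather must cover all counties")

  beta <- county_beta_truth(config, sdoh)
  set.seed(stage_seed(config$seed, "events"))
  if (config$spatial_rho > 0) {
    if (is.null(adjacency)) stop("adjacency required when spatial_rho > 0")
    w_row <- adjacency / pmax(1, rowSums(adjacency))
    e <- rnorm(config$n_counties, 0, config$spatial_sd)
    beta <- beta + as.numeric(
      solve(diag(config$n_counties) - config$spatial_rho * w_row, e)
    )
  }
  if (config$beta_noise_sd > 0) {
    beta <- beta + rnorm(config$n_counties, 0, config$beta_noise_sd)
  }
  names(beta) <- ids

  wt <- data.table::as.data.table(weather)
  wt[, date := as.Date(date)]
  wt[, tbar := mean(tmean_c), by = county_id]
  wt[, lambda := config$baseline_rate *
       exp(beta[county_id] * (tmean_c - tbar))]
  counts <- rpois(nrow(wt), wt$lambda)
  idx <- rep(seq_len(nrow(wt)), counts)
  n_ev <- length(idx)
  events <- data.frame(
    patient_id = seq_len(n_ev),
    date = wt$date[idx],
    icd9 = unname(OUTCOME_ICD9[config$outcome]),
    outcome = config$outcome,
    stream = config$stream,
    county_id = wt$county_id[idx],
    zip_id = paste0("Z", wt$county_id[idx]),
    stringsAsFactors = FALSE
  )

  if (config$dup_frac > 0 && n_ev > 0) {
    window <- OUTCOME_DEDUP_WINDOWS[[config$outcome]]
    pick <- runif(n_ev) < config$dup_frac
    lag_days <- sample(seq_len(window - 1), n_ev, replace = TRUE)
    dup_date <- events$date + lag_days
    bounds <- season_bounds(events$date, config$season)
    keep <- pick & dup_date <= bounds$end
    if (any(keep)) {
      dups <- events[keep, , drop = FALSE]
      dups$date <- dup_date[keep]
      events <- rbind(events, dups)
    }
  }
  events <- events[order(events$county_id, events$date, events$patient_id), ]
  rownames(events) <- NULL

  list(
    events = events,
    truth = list(
      county_beta = beta, gamma = config$gamma, gamma0 = config$gamma0,
      sdoh_table = sdoh
    )
  )
}

#' Noise-free planted county log-odds ratios
#'
#' Recomputes `gamma0 + sum_v gamma_v * sdoh_cv`, the deterministic part of
#' the planted county log-OR surface, from the configuration and covariate
#' table alone.
#'
#' @inheritParams generate_events
#' @return numeric vector, one value per county (in `sdoh` row order).
#' @export
county_beta_truth <- function(config, sdoh) {
  beta <- rep(config$gamma0, nrow(sdoh))
  if (length(config$gamma)) {
    miss <- setdiff(names(config$gamma), names(sdoh))
    if (length(miss)) stop("gamma names absent from SDOH table: ",
                           paste(miss, collapse = ", "))
    for (v in names(config$gamma)) {
      beta <- beta + config$gamma[[v]] * sdoh[[v]]
    }
  }
  beta
}

#' Generate every synthetic input in one call
#'
#' Convenience wrapper running weather, SDOH, adjacency, and event generation
#' with one configuration.
#'
#' @param config a [sim_config()].
#' @return list with `weather`, `sdoh`, `adjacency`, `events`, `truth`.
#' @export
simulate_inputs <- function(config) {
  weather <- generate_weather(config)
  sdoh <- generate_sdoh(config)
  adjacency <- generate_adjacency(config$n_rows, config$n_cols)
  ev <- generate_events(config, weather, sdoh, adjacency)
  list(weather = weather, sdoh = sdoh, adjacency = adjacency,
       events = ev$events, truth = ev$truth)
}
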