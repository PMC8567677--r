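#' Pipeline run configuration
#'
#' Collects every tunable constant of the end-to-end workflow: the warm
#' season bounds, the exposure metric and lag (fixed or chosen by pooled
#' AIC), the minimum county case count, the correlation-pruning threshold,
#' the Moran permutation count, the significance level, the outcome
#' deduplication windows, and the global seed from which every stage seed is
#' derived.
#'
#' @param out_dir directory for all written artifacts.
#' @param simulate logical; generate synthetic inputs (`TRUE`, default) or
#'   read them from `paths`.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param paths named list of input file paths (`events`, `weather`, `sdoh`,
#'   `adjacency`) used when `simulate = FALSE`.
#' @param season season start/end as "MM-DD".
#' @param metric exposure metric (`"tmax"`, `"tmean"`, `"tmin"`, `"himax"`)
#'   or `"auto"` to scan metrics and lags by pooled AIC.
#' @param lag exposure lag in days (ignored when `metric = "auto"`).
#' @param max_lag largest lag scanned under `metric = "auto"`.
#' @param min_cases minimum retained strata per county (default 30).
#' @param threshold correlation-pruning threshold (default 0.7).
#' @param drop optional explicit pruning list.
#' @param n_permutations Moran permutation count (default 999).
#' @param alpha significance level (default 0.05).
#' @param use_log_or regress log odds ratios in stage 2 (default `FALSE`).
#' @param dedup_windows named outcome-to-days map (default
#'   [OUTCOME_DEDUP_WINDOWS]).
#' @param seed global integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("heatvuln_run_"),
                       simulate = TRUE, sim = sim_config(seed = seed),
                       paths = list(), season = c("05-01", "09-30"),
                       metric = "tmean", lag = 0, max_lag = 10,
                       min_cases = 30, threshold = 0.7, drop = NULL,
                       n_permutations = 999, alpha = 0.05,
                       use_log_or = FALSE,
                       dedup_windows = OUTCOME_DEDUP_WINDOWS, seed = 1L) {
  cfg <- list(
    out_dir = out_dir, simulate = simulate, sim = sim, paths = paths,
    season = season, metric = metric, lag = lag, max_lag = max_lag,
    min_cases = min_cases, threshold = threshold, drop = drop,
    n_permutations = n_permutations, alpha = alpha, use_log_or = use_log_or,
    dedup_windows = dedup_windows, seed = as.integer(seed)
  )
  if (!cfg$metric %in% c("auto", EXPOSURE_METRICS)) {
    stop("metric must be 'auto' or one of: ",
         paste(EXPOSURE_METRICS, collapse = ", "))
  }
  if (cfg$min_cases < 1) stop("min_cases must be positive")
  if (cfg$threshold <= 0) stop("threshold must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$n_permutations < 1) stop("n_permutations must be positive")
  if (cfg$lag < 0 || cfg$max_lag < 0) stop("lags must be non-negative")
  if (!cfg$simulate) {
    need <- c("events", "weather", "sdoh", "adjacency")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss)) stop("paths must name input files: ",
                           paste(miss, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Run the two-stage heat-vulnerability pipeline
#'
#' Executes simulate (or load) -> exposure -> deduplication -> referent
#' matching and county conditional-logistic odds ratios -> SDOH pruning,
#' stepwise selection, and aspatial/spatial model choice, writing every
#' intermediate artifact as CSV plus a JSON run report with record counts at
#' each filter. The whole run is reproducible from the configuration and its
#' seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `report`, `exposure`, `events`,
#'   `county_ors`, `stage2`, `metric`, `lag`, and (when simulated) `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out_dir, name)
  report <- list(seed = config$seed)
  truth <- NULL

  if (config$simulate) {
    message("[simulate] generating synthetic inputs (seed ", config$seed, ")")
    sim <- simulate_inputs(config$sim)
    weather <- sim$weather
    events_raw <- sim$events
    sdoh <- sim$sdoh
    w <- sim$adjacency
    truth <- sim$truth
    write_weather(weather, outfile("weather.csv"))
    write_events(events_raw, outfile("events_raw.csv"))
    write_sdoh(sdoh, outfile("sdoh.csv"))
    write_adjacency(w, outfile("adjacency.csv"))
  } else {
    message("[load] reading inputs")
    weather <- read_weather(config$paths$weather)
    events_raw <- read_events(config$paths$events)
    sdoh <- read_sdoh(config$paths$sdoh)
    w <- read_adjacency(config$paths$adjacency, ids = sdoh$county_id)
  }
  report$events_read <- nrow(events_raw)

  message("[exposure] building county exposure series")
  exposure <- build_exposure(weather)
  write_exposure(exposure, outfile("exposure.csv"))
  report$exposure_rows <- nrow(exposure)

  message("[casecrossover] deduplicating events")
  events <- deduplicate_events(events_raw, config$dedup_windows)
  report$events_removed_dedup <- attr(events, "n_removed")
  report$events_after_dedup <- nrow(events)
  write_events(events, outfile("events_dedup.csv"))

  if (config$metric == "auto") {
    message("[casecrossover] scanning metrics and lags by pooled AIC")
    sel <- select_best_metric_lag(
      events, exposure, lags = 0:config$max_lag,
      min_cases = config$min_cases, season = config$season
    )
    metric <- sel$metric
    lag <- sel$lag
    write.csv(sel$aic_table, outfile("aic_grid.csv"), row.names = FALSE)
    report$aic_grid_cells <- nrow(sel$aic_table)
  } else {
    metric <- config$metric
    lag <- config$lag
  }
  report$metric <- metric
  report$lag <- lag

  message(sprintf("[casecrossover] fitting county ORs (%s, lag %d)",
                  metric, lag))
  strata <- build_strata(events, exposure, metric, lag, config$season)
  report$strata_built <- nrow(strata$x)
  report$referents_built <- 3L * nrow(strata$x)
  report$strata_dropped_incomplete <- strata$n_dropped_incomplete
  report$strata_dropped_exposure <- strata$n_dropped_exposure
  ors <- estimate_county_ors(events, exposure, metric, lag,
                             config$min_cases, config$season)
  write_county_ors(ors, outfile("county_or.csv"))
  report$counties_fitted <- nrow(ors)
  report$counties_excluded_min_cases <- nrow(attr(ors, "excluded"))

  if (nrow(ors) == 0) {
    message("[spatial] skipped: no county met the minimum case count")
    report$stage2 <- "skipped: no county odds ratios"
    stage2 <- NULL
  } else {
    message("[spatial] stage-2 SDOH models")
    stage2 <- stage2_analysis(
      ors, sdoh, w, threshold = config$threshold, drop = config$drop,
      alpha = config$alpha, n_permutations = config$n_permutations,
      seed = stage_seed(config$seed, "moran"),
      use_log_or = config$use_log_or
    )
    write_stage2(stage2, outfile("stage2.csv"))
    report$stage2 <- lapply(stage2$results, function(r) {
      list(
        outcome = r$outcome, stream = r$stream, model_type = r$model_type,
        n_counties = length(r$counties),
        variables_pruned = length(r$pruned),
        variables_selected = length(r$variables),
        aic = r$aic, moran_p = r$moran_p, ks_p = r$ks_p
      )
    })
    report$stage2_skipped <- stage2$skipped
  }

  jsonlite::write_json(report, outfile("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    report = report, exposure = exposure, events = events, county_ors = ors,
    stage2 = stage2, metric = metric, lag = lag, truth = truth
  ))
}
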