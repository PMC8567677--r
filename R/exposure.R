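#' Collapse weather observations to daily exposure metrics
#'
#' Aggregates temperature observations (hourly or already-daily) to one row
#' per cell per day carrying daily maximum, mean, and minimum temperature and
#' the daily maximum Heat Index, all in degrees Celsius. The Heat Index is
#' evaluated in Fahrenheit at each observation's concurrent humidity and the
#' daily maximum converted back to Celsius; with a single observation per day
#' this reduces to the Heat Index of the daily maximum temperature at the
#' daily humidity.
#'
#' @param obs data.frame with columns `cell_id`, `date` (Date or ISO string),
#'   `temp_c`, `rh_pct`, and optionally `hour`.
#' @return data.frame with columns `cell_id`, `date`, `tmax_c`, `tmean_c`,
#'   `tmin_c`, `himax_c`.
#' @export
daily_metrics <- function(obs) {
  req <- c("cell_id", "date", "temp_c", "rh_pct")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("weather observations lack columns: ", paste(miss, collapse = ", "))
  if (nrow(obs) == 0) stop("no weather observations supplied")
  dt <- data.table::as.data.table(obs)
  dt[, date := as.Date(date)]
  if (anyNA(dt$temp_c) || anyNA(dt$rh_pct)) {
    bad <- dt[is.na(temp_c) | is.na(rh_pct)][1]
    stop(sprintf(
      "missing weather value for cell %s on %s", bad$cell_id, format(bad$date)
    ))
  }
  dt[, hi_c := heat_index_c(temp_c, rh_pct)]
  out <- dt[, .(
    tmax_c = max(temp_c), tmean_c = mean(temp_c), tmin_c = min(temp_c),
    himax_c = max(hi_c)
  ), by = .(cell_id, date)]
  data.table::setorder(out, cell_id, date)
  as.data.frame(out)
}

#' Population-weighted county exposure series
#'
#' Aggregates cell/ZIP-level daily exposure metrics to the county level using
#' population weights, emulating population-weighted exposure built from ZIP
#' code centroids: the county value of each metric on each day is the
#' population-weighted mean across the county's ZIPs.
#'
#' @param cell_series data.frame from [daily_metrics()] (or the same schema)
#'   whose `cell_id` values are ZIP identifiers.
#' @param weights data.frame with columns `zip_id`, `county_id`, `population`
#'   (non-negative; every ZIP maps to exactly one county).
#' @return exposure series data.frame with columns `county_id`, `date`,
#'   `tmax_c`, `tmean_c`, `tmin_c`, `himax_c`.
#' @export
population_weighted_series <- function(cell_series, weights) {
  if (any(weights$population < 0)) stop("populations must be non-negative")
  if (anyDuplicated(weights$zip_id)) stop("each ZIP must map to exactly one county")
  tot <- tapply(weights$population, weights$county_id, sum)
  if (any(tot <= 0)) {
    stop("county with zero total population: ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  }
  dt <- data.table::as.data.table(cell_series)
  dt[, date := as.Date(date)]
  w <- data.table::as.data.table(weights)
  unmatched <- setdiff(dt$cell_id, w$zip_id)
  if (length(unmatched)) {
    stop("cells without population weights: ", paste(unmatched, collapse = ", "))
  }
  dt <- merge(dt, w, by.x = "cell_id", by.y = "zip_id")
  out <- dt[, .(
    tmax_c = sum(tmax_c * population) / sum(population),
    tmean_c = sum(tmean_c * population) / sum(population),
    tmin_c = sum(tmin_c * population) / sum(population),
    himax_c = sum(himax_c * population) / sum(population)
  ), by = .(county_id, date)]
  data.table::setorder(out, county_id, date)
  as.data.frame(out)
}

#' Exposure series from daily county weather
#'
#' Builds the canonical county-by-day exposure table from a daily weather
#' table that already carries max/mean/min temperature and relative humidity,
#' adding the daily maximum Heat Index computed from the daily maximum
#' temperature and the day's humidity.
#'
#' @param weather data.frame with columns `county_id`, `date`, `tmax_c`,
#'   `tmean_c`, `tmin_c`, `rh_pct`.
#' @return exposure series data.frame (`county_id`, `date`, `tmax_c`,
#'   `tmean_c`, `tmin_c`, `himax_c`).
#' @export
build_exposure <- function(weather) {
  req <- c("county_id", "date", "tmax_c", "tmean_c", "tmin_c", "rh_pct")
  miss <- setdiff(req, names(weather))
  if (length(miss)) stop("weather table lacks columns: ", paste(miss, collapse = ", "))
  bad <- weather$tmin_c > weather$tmean_c | weather$tmean_c > weather$tmax_c
  if (any(bad)) stop("tmin <= tmean <= tmax violated on ", sum(bad), " row(s)")
  out <- data.frame(
    county_id = weather$county_id,
    date = as.Date(weather$date),
    tmax_c = weather$tmax_c,
    tmean_c = weather$tmean_c,
    tmin_c = weather$tmin_c,
    himax_c = heat_index_c(weather$tmax_c, weather$rh_pct)
  )
  out[order(out$county_id, out$date), , drop = FALSE]
}

EXPOSURE_METRICS <- c("tmax", "tmean", "tmin", "himax")

#' Lagged exposure table
#'
#' Expands an exposure series into a county x date x lag table: the lag-k
#' value on date d is the metric observed on d - k. Lags that reach before
#' the first covered date of a county's season are missing; strata touching
#' them are dropped downstream rather than imputed.
#'
#' @param series exposure series from [build_exposure()] or
#'   [population_weighted_series()].
#' @param max_lag maximum lag in days (default 10).
#' @return data.frame with columns `county_id`, `date`, `lag`, `tmax_c`,
#'   `tmean_c`, `tmin_c`, `himax_c` (NA where the lagged date is uncovered).
#' @export
build_lag_matrix <- function(series, max_lag = 10) {
  if (max_lag < 0) stop("max_lag must be non-negative")
  dt <- data.table::as.data.table(series)
  dt[, date := as.Date(date)]
  out <- data.table::rbindlist(lapply(0:max_lag, function(k) {
    shifted <- data.table::copy(dt)
    shifted[, date := date + k]
    res <- merge(
      dt[, .(county_id, date)], shifted,
      by = c("county_id", "date"), all.x = TRUE
    )
    res[, lag := k]
    res
  }))
  data.table::setcolorder(out, c("county_id", "date", "lag"))
  data.table::setorder(out, county_id, date, lag)
  as.data.frame(out)
}

# Fast lagged-exposure lookup used by stratum construction: returns the
# metric value at (county, date - lag), NA when uncovered.
exposure_lookup <- function(series, metric = EXPOSURE_METRICS) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_c")
  key <- paste(series$county_id, as.integer(as.Date(series$date)), sep = "|")
  vals <- series[[col]]
  function(county_id, dates, lag = 0) {
    q <- paste(county_id, as.integer(as.Date(dates)) - lag, sep = "|")
    vals[match(q, key)]
  }
}
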