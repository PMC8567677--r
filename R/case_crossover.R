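#' Outcome-specific deduplication windows (days)
#'
#' Subsequent visits by the same patient within 7 days (dehydration,
#' heat-related illness, respiratory disease) or 28 days (cardiovascular and
#' acute renal disease) of a retained visit are treated as the same illness
#' episode and removed.
#'
#' @export
OUTCOME_DEDUP_WINDOWS <- c(
  cardiovascular = 28, dehydration = 7, heat_related = 7,
  acute_renal = 28, respiratory = 7
)

#' Classify an ICD-9 code into a heat-sensitive outcome class
#'
#' Range membership on the numeric code: cardiovascular disease (390-459),
#' dehydration (276.51), heat-related illness (992 and E-codes E900.0,
#' E900.1, E900.9), acute renal disease (584.5-584.9), respiratory disease
#' (460-519). Codes outside every range, and unparseable codes (with a
#' warning), classify to `NA`.
#'
#' @param icd9 character vector of ICD-9 / E-code strings.
#' @return character vector of outcome classes (`"cardiovascular"`,
#'   `"dehydration"`, `"heat_related"`, `"acute_renal"`, `"respiratory"`) or
#'   `NA_character_`.
#' @export
classify_outcome <- function(icd9) {
  code <- trimws(as.character(icd9))
  out <- rep(NA_character_, length(code))

  ecode <- toupper(code) %in% c("E900.0", "E900.1", "E900.9")
  out[ecode] <- "heat_related"

  # other well-formed E/V codes are valid ICD-9 but outside every listed
  # range: silently unclassified
  other_ev <- !ecode & grepl("^[EV][0-9]+(\\.[0-9]+)?$", toupper(code))

  plain <- !ecode & !other_ev
  num <- suppressWarnings(as.numeric(code[plain]))
  bad <- is.na(num) & nzchar(code[plain])
  if (any(bad)) {
    warning("unparseable ICD-9 code(s): ",
            paste(unique(code[plain][bad]), collapse = ", "))
  }
  cls <- rep(NA_character_, length(num))
  major <- floor(num)
  cls[!is.na(num) & num == 276.51] <- "dehydration"
  cls[!is.na(num) & major == 992] <- "heat_related"
  cls[!is.na(num) & major == 584 & num >= 584.5 & num <= 584.9] <- "acute_renal"
  cls[!is.na(num) & is.na(cls) & major >= 390 & major <= 459] <- "cardiovascular"
  cls[!is.na(num) & is.na(cls) & major >= 460 & major <= 519] <- "respiratory"
  out[plain] <- cls
  out
}

#' Remove repeat visits within the episode window
#'
#' Scans each patient-outcome stream chronologically and drops any visit
#' falling fewer than the outcome's window days after the last retained
#' visit; the first visit is always retained. Idempotent.
#'
#' @param events event data.frame with `patient_id`, `outcome`, `date` (and
#'   any other columns, carried through).
#' @param windows named vector of window lengths in days per outcome
#'   (default [OUTCOME_DEDUP_WINDOWS]).
#' @return the retained events, in (patient, outcome, date) order, with
#'   attribute `n_removed`.
#' @export
deduplicate_events <- function(events, windows = OUTCOME_DEDUP_WINDOWS) {
  if (nrow(events) == 0) return(events)
  unknown <- setdiff(unique(events$outcome), names(windows))
  if (length(unknown)) stop("no deduplication window for outcome: ",
                            paste(unknown, collapse = ", "))
  ev <- events[order(events$patient_id, events$outcome, events$date), ,
               drop = FALSE]
  grp <- paste(ev$patient_id, ev$outcome, sep = "\r")
  r <- rle(grp)
  sizes <- r$lengths
  starts <- cumsum(sizes) - sizes + 1
  keep <- rep(TRUE, nrow(ev))
  w <- windows[ev$outcome]
  date_num <- as.numeric(as.Date(ev$date))

  two <- which(sizes == 2)
  if (length(two)) {
    second <- starts[two] + 1
    keep[second] <- (date_num[second] - date_num[second - 1]) >= w[second]
  }
  for (g in which(sizes > 2)) {
    idx <- starts[g]:(starts[g] + sizes[g] - 1)
    last <- date_num[idx[1]]
    for (i in idx[-1]) {
      if (date_num[i] - last < w[i]) keep[i] <- FALSE else last <- date_num[i]
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Time-stratified bidirectional referent dates
#'
#' Partitions each warm season into fixed 28-day comparison windows anchored
#' at the season start and matches each case to the other days of its
#' stratum that share its day of the week: exactly 3 referents per case,
#' drawn from both before and after the event, each at an offset whose
#' magnitude is 7, 14, or 21 days. Because the strata are a fixed calendar
#' partition (not anchored on the case), every day of a stratum carries the
#' same referent set, which makes the matched sets exchangeable and the
#' conditional likelihood free of the selection bias that case-anchored
#' referent rules incur under a seasonal exposure trend; it also yields the
#' design's exact 3:1 control-to-case ratio. Cases falling in a trailing
#' incomplete stratum (a season length that is not a multiple of 28 days)
#' have fewer than 3 same-weekday stratum mates and are dropped, flagged as
#' `NA` rows here and counted downstream. The scheme is deterministic, so
#' referent sets are trivially reproducible and row-order invariant.
#'
#' @param case_dates Date vector of case days (each within its warm season).
#' @param season season start/end as "MM-DD".
#' @param stratum_days comparison-window length in days (default 28).
#' @return n x 3 matrix of referent dates (numeric Dates); `NA` rows mark
#'   cases in an incomplete stratum.
#' @export
select_referents <- function(case_dates, season = c("05-01", "09-30"),
                             stratum_days = 28) {
  if (stratum_days %% 7 != 0 || stratum_days < 14) {
    stop("stratum_days must be a multiple of 7 days of at least 14")
  }
  case_dates <- as.Date(case_dates)
  bounds <- season_bounds(case_dates, season)
  if (any(case_dates < bounds$start | case_dates > bounds$end)) {
    stop("case dates must fall within the warm season")
  }
  idx <- as.numeric(case_dates - bounds$start)
  block <- idx %/% stratum_days
  week <- (idx %% stratum_days) %/% 7
  n_weeks <- stratum_days %/% 7
  # Offsets to the other same-weekday days of the stratum, by week-in-block.
  offsets <- t(vapply(seq_len(n_weeks) - 1, function(wk) {
    7 * (setdiff(seq_len(n_weeks) - 1, wk) - wk)
  }, numeric(n_weeks - 1)))
  complete <- as.numeric(bounds$end - bounds$start) + 1 >=
    (block + 1) * stratum_days
  out <- matrix(as.numeric(case_dates), length(case_dates), n_weeks - 1) +
    offsets[week + 1, , drop = FALSE]
  out[!complete, ] <- NA_real_
  out
}

#' Build matched case-referent strata
#'
#' Assembles one 1:3 matched stratum per retained event: the exposure metric
#' at the case day and its three referent days, each lagged by `lag` days.
#' Strata with any missing exposure (e.g. a lag reaching before the season's
#' first covered day) or an unresolvable referent are dropped and counted.
#'
#' @param events deduplicated event data.frame (`patient_id`, `date`,
#'   `outcome`, `stream`, `county_id`).
#' @param exposure county exposure series (see [build_exposure()]).
#' @param metric one of `"tmax"`, `"tmean"`, `"tmin"`, `"himax"`.
#' @param lag exposure lag in days (0-10 in the standard analysis).
#' @param season season bounds as "MM-DD".
#' @return object of class `matched_strata`: list with `x` (n x 4 exposure
#'   matrix, case column first), `county_id`, `outcome`, `stream`,
#'   `case_date`, `metric`, `lag`, and drop counters.
#' @export
build_strata <- function(events, exposure, metric = "tmean", lag = 0,
                         season = c("05-01", "09-30")) {
  metric <- match.arg(metric, EXPOSURE_METRICS)
  if (lag < 0) stop("lag must be non-negative")
  lookup <- exposure_lookup(exposure, metric)
  case_dates <- as.Date(events$date)
  refs <- select_referents(case_dates, season)
  x <- cbind(
    lookup(events$county_id, case_dates, lag),
    lookup(events$county_id, refs[, 1], lag),
    lookup(events$county_id, refs[, 2], lag),
    lookup(events$county_id, refs[, 3], lag)
  )
  ref_missing <- rowSums(is.na(refs)) > 0
  expo_missing <- !ref_missing & rowSums(is.na(x)) > 0
  ok <- !ref_missing & !expo_missing
  structure(list(
    x = x[ok, , drop = FALSE],
    county_id = events$county_id[ok],
    outcome = events$outcome[ok],
    stream = events$stream[ok],
    case_date = case_dates[ok],
    metric = metric, lag = lag,
    n_dropped_incomplete = sum(ref_missing),
    n_dropped_exposure = sum(expo_missing)
  ), class = "matched_strata")
}

#' @export
print.matched_strata <- function(x, ...) {
  cat(sprintf(
    "<matched_strata> %d strata (1 case : 3 referents), metric=%s lag=%d\n",
    nrow(x$x), x$metric, x$lag
  ))
  cat(sprintf("  dropped: %d (incomplete stratum), %d (missing exposure)\n",
              x$n_dropped_incomplete, x$n_dropped_exposure))
  invisible(x)
}

# Conditional logistic log-likelihood for 1:m matched strata with a single
# scalar exposure; x is the stratum exposure matrix, case column first.
clogit_loglik <- function(beta, x) {
  s <- beta * x
  m <- do.call(pmax, as.data.frame(s))
  sum(s[, 1] - m - log(rowSums(exp(s - m))))
}

#' Conditional logistic regression for matched strata
#'
#' Maximises the conditional (matched-set) log-likelihood
#' `sum_s [beta * x_case - log sum_j exp(beta * x_j)]` for a single scalar
#' exposure by Newton-Raphson from `beta = 0`, with the standard error taken
#' from the inverse observed information and `AIC = 2 - 2 * loglik`. If the
#' iterates escape beyond |beta| = 10 (which happens when the case exposure
#' is the stratum maximum in every stratum) the fit is flagged
#' non-converged with beta capped. Strata with no within-stratum exposure
#' variation contribute nothing; if every stratum is constant the fit is
#' flagged degenerate with `beta = 0` and infinite standard error.
#'
#' @param strata a `matched_strata` object, or a bare numeric matrix of
#'   stratum exposures with the case in column 1.
#' @param tol convergence tolerance on the Newton step.
#' @param max_iter maximum Newton iterations.
#' @return list: `beta` (log-OR per unit exposure), `se`, `or_value`,
#'   `loglik`, `aic`, `n_strata`, `converged`, `degenerate`, `n_iter`.
#' @export
conditional_logistic_fit <- function(strata, tol = 1e-10, max_iter = 50) {
  x <- if (inherits(strata, "matched_strata")) strata$x else as.matrix(strata)
  if (nrow(x) == 0) stop("no strata to fit")
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) {
    ll0 <- clogit_loglik(0, x)
    return(list(beta = 0, se = Inf, or_value = 1, loglik = ll0,
                aic = 2 - 2 * ll0, n_strata = nrow(x), converged = FALSE,
                degenerate = TRUE, n_iter = 0L))
  }
  beta <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    s <- beta * xc
    m <- do.call(pmax, as.data.frame(s))
    e <- exp(s - m)
    p <- e / rowSums(e)
    mu <- rowSums(p * xc)
    v <- rowSums(p * xc^2) - mu^2
    score <- sum(xc[, 1] - mu)
    info <- sum(v)
    if (!is.finite(info) || info <= 0) break
    step <- score / info
    beta <- beta + step
    if (abs(beta) > 10) {
      beta <- sign(beta) * 10
      break
    }
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  s <- beta * xc
  m <- do.call(pmax, as.data.frame(s))
  e <- exp(s - m)
  p <- e / rowSums(e)
  mu <- rowSums(p * xc)
  info <- sum(rowSums(p * xc^2) - mu^2)
  ll <- clogit_loglik(beta, x)
  list(
    beta = beta, se = if (info > 0) 1 / sqrt(info) else Inf,
    or_value = exp(beta), loglik = ll, aic = 2 - 2 * ll,
    n_strata = nrow(x), converged = converged, degenerate = FALSE,
    n_iter = iter
  )
}

#' Per-county odds ratio estimates
#'
#' Fits the conditional logistic model independently within each county (and
#' outcome/stream cell present in the events), returning one odds-ratio
#' estimate per county with at least `min_cases` retained strata; smaller
#' counties are omitted and reported in the `excluded` attribute, mirroring
#' the mapping convention that counties under 30 cases are left blank.
#'
#' @inheritParams build_strata
#' @param min_cases minimum retained strata per county (default 30).
#' @return data.frame with columns `county_id`, `outcome`, `stream`,
#'   `metric`, `lag`, `beta`, `se`, `or_value`, `n_cases`, `aic`,
#'   `converged`; attribute `excluded` lists omitted county cells.
#' @export
estimate_county_ors <- function(events, exposure, metric = "tmean", lag = 0,
                                min_cases = 30,
                                season = c("05-01", "09-30")) {
  st <- build_strata(events, exposure, metric, lag, season)
  cell <- paste(st$county_id, st$outcome, st$stream, sep = "\r")
  idx <- split(seq_along(cell), cell)
  rows <- lapply(idx, function(i) {
    fit <- conditional_logistic_fit(st$x[i, , drop = FALSE])
    data.frame(
      county_id = st$county_id[i[1]], outcome = st$outcome[i[1]],
      stream = st$stream[i[1]], metric = metric, lag = lag,
      beta = fit$beta, se = fit$se, or_value = fit$or_value,
      n_cases = fit$n_strata, aic = fit$aic, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  small <- out$n_cases < min_cases
  res <- out[!small, , drop = FALSE]
  res <- res[order(res$county_id, res$outcome, res$stream), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- out[small, c("county_id", "outcome", "stream",
                                        "n_cases"), drop = FALSE]
  res
}

#' Choose the exposure metric and lag by pooled AIC
#'
#' Fits the county models for every combination of the four exposure metrics
#' and lags 0 to `max_lag`, sums the county AICs within each combination,
#' and returns the combination with the lowest pooled AIC together with the
#' full AIC grid (4 metrics x 11 lags = 44 cells at the defaults). To keep
#' the AICs comparable across the grid, the scan is restricted to the events
#' whose whole stratum remains estimable at the longest candidate lag, so
#' every cell is fitted on exactly the same matched strata.
#'
#' @inheritParams estimate_county_ors
#' @param metrics exposure metrics to scan.
#' @param lags integer lags to scan.
#' @return list: `metric`, `lag`, `aic_table` (data.frame `metric`, `lag`,
#'   `total_aic`, `n_counties`, `n_strata`).
#' @export
select_best_metric_lag <- function(events, exposure,
                                   metrics = EXPOSURE_METRICS, lags = 0:10,
                                   min_cases = 30,
                                   season = c("05-01", "09-30")) {
  # common estimable set: drop events whose stratum reaches before the
  # earliest covered day at the maximum lag
  refs <- select_referents(as.Date(events$date), season)
  earliest <- pmin(as.numeric(as.Date(events$date)), refs[, 1], refs[, 2],
                   refs[, 3])
  start_num <- as.numeric(season_bounds(as.Date(events$date), season)$start)
  ok <- !is.na(earliest) & (earliest - max(lags) >= start_num)
  events <- events[ok, , drop = FALSE]

  grid <- expand.grid(metric = metrics, lag = lags,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    ors <- estimate_county_ors(events, exposure, grid$metric[g], grid$lag[g],
                               min_cases, season)
    data.frame(
      metric = grid$metric[g], lag = grid$lag[g],
      total_aic = if (nrow(ors)) sum(ors$aic) else Inf,
      n_counties = nrow(ors),
      n_strata = if (nrow(ors)) sum(ors$n_cases) else 0L,
      stringsAsFactors = FALSE
    )
  })
  aic_table <- do.call(rbind, rows)
  best <- which.min(aic_table$total_aic)
  list(metric = aic_table$metric[best], lag = aic_table$lag[best],
       aic_table = aic_table)
}
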