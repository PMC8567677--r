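#' @import data.table
#' @importFrom stats aggregate AIC coef complete.cases cor ks.test lm lm.fit
#'   logLik optimize pnorm pt rnorm rpois runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

# Lehmer (Park-Miller) modulus; all hash arithmetic stays below 2^53 so it is
# exact in doubles.
.LEHMER_M <- 2147483647
.LEHMER_A <- 48271

# One multiplicative step of the Lehmer generator, vectorised.
lehmer_step <- function(h) (h * .LEHMER_A) %% .LEHMER_M

#' Derive a per-stage seed from a global seed
#'
#' Expands one pipeline seed into independent stage seeds through a fixed
#' keyed hash, so individual stages can be rerun in isolation with the same
#' stream of randomness.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  chars <- utf8ToInt(as.character(stage))
  h <- (abs(as.numeric(seed)) %% .LEHMER_M) + 1
  for (ch in chars) h <- lehmer_step((h + ch) %% .LEHMER_M)
  as.integer(lehmer_step(h))
}

#' Temperature unit conversions
#'
#' @param x temperature values.
#' @return converted temperatures.
#' @export
celsius_to_fahrenheit <- function(x) x * 9 / 5 + 32

#' @rdname celsius_to_fahrenheit
#' @export
fahrenheit_to_celsius <- function(x) (x - 32) * 5 / 9

#' Warm-season calendar dates
#'
#' Enumerates the daily dates of the analysis season (default May 1 through
#' September 30) for each study year.
#'
#' @param years integer vector of calendar years.
#' @param season length-2 character vector of "MM-DD" season start and end.
#' @return Date vector of all in-season days, ordered by year then day.
#' @export
season_dates <- function(years, season = c("05-01", "09-30")) {
  if (length(years) == 0) stop("`years` must contain at least one year")
  starts <- as.Date(paste0(years, "-", season[1]))
  ends <- as.Date(paste0(years, "-", season[2]))
  if (any(ends <= starts)) stop("season end must fall after season start within a year")
  do.call(c, lapply(seq_along(years), function(i) seq(starts[i], ends[i], by = "day")))
}

# Season bounds lookup: for a vector of dates, the season start/end of the
# year each date falls in.
season_bounds <- function(dates, season = c("05-01", "09-30")) {
  yr <- as.integer(format(dates, "%Y"))
  list(
    start = as.Date(paste0(yr, "-", season[1])),
    end = as.Date(paste0(yr, "-", season[2]))
  )
}

#' County identifiers used by the synthetic generators
#'
#' @param n number of counties.
#' @return character vector `"C001"`, `"C002"`, ... in lattice row-major
#'   order.
#' @export
county_ids <- function(n) sprintf("C%03d", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
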