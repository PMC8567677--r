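#' Heat Index (apparent temperature)
#'
#' Computes the National Weather Service Heat Index from air temperature in
#' degrees Fahrenheit and relative humidity in percent. For temperatures at
#' or above 80 degrees F the nine-term Rothfusz regression polynomial is used,
#' with the standard NWS adjustments: a subtraction for very dry air
#' (RH < 13\%, T between 80 and 112 F) and an addition for very humid air
#' (RH > 85\%, T between 80 and 87 F). Below 80 F the simple-formula average
#' `0.5 * (T + 61 + (T - 68) * 1.2 + R * 0.094)` is returned, which tracks
#' air temperature closely in mild conditions.
#'
#' @param temperature_f air temperature in degrees Fahrenheit.
#' @param relative_humidity relative humidity in percent, within \[0, 100\].
#' @param adjust logical; apply the low/high-humidity adjustment terms
#'   (default `TRUE`). With `adjust = FALSE` the bare polynomial is returned
#'   for every input at or above 80 F.
#' @return heat index in degrees Fahrenheit, vectorised over inputs.
#' @examples
#' heat_index(90, 60)
#' @export
heat_index <- function(temperature_f, relative_humidity, adjust = TRUE) {
  n <- max(length(temperature_f), length(relative_humidity))
  t <- rep_len(as.numeric(temperature_f), n)
  r <- rep_len(as.numeric(relative_humidity), n)
  if (any(!is.finite(r)) || any(r < 0 | r > 100)) {
    stop("relative humidity must lie within [0, 100]")
  }

  hi <- 0.5 * (t + 61 + (t - 68) * 1.2 + r * 0.094)

  hot <- t >= 80
  if (any(hot)) {
    th <- t[hot]
    rh <- r[hot]
    poly <- -42.379 + 2.049015 * th + 10.143331 * rh - 0.224755 * th * rh -
      6.83783e-3 * th^2 - 5.481717e-2 * rh^2 + 1.22874e-3 * th^2 * rh +
      8.5282e-4 * th * rh^2 - 1.99e-6 * th^2 * rh^2
    if (adjust) {
      dry <- rh < 13 & th >= 80 & th <= 112
      if (any(dry)) {
        poly[dry] <- poly[dry] -
          ((13 - rh[dry]) / 4) * sqrt((17 - abs(th[dry] - 95)) / 17)
      }
      humid <- rh > 85 & th >= 80 & th <= 87
      if (any(humid)) {
        poly[humid] <- poly[humid] +
          ((rh[humid] - 85) / 10) * ((87 - th[humid]) / 2)
      }
    }
    hi[hot] <- poly
  }
  hi
}

#' Heat Index in Celsius from Celsius inputs
#'
#' Convenience wrapper: converts to Fahrenheit, evaluates [heat_index()], and
#' converts back. Odds ratios downstream are expressed per degree Celsius, so
#' all exposure series carry Celsius values.
#'
#' @inheritParams heat_index
#' @param temperature_c air temperature in degrees Celsius.
#' @return heat index in degrees Celsius.
#' @export
heat_index_c <- function(temperature_c, relative_humidity, adjust = TRUE) {
  fahrenheit_to_celsius(
    heat_index(celsius_to_fahrenheit(temperature_c), relative_humidity, adjust)
  )
}
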