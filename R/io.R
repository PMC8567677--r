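#' Read and write pipeline artifacts
#'
#' All intermediate artifacts are plain CSV with ISO-8601 dates and Celsius
#' temperatures; readers validate the schema and report the offending column
#' and row on violation, so `read(write(x))` recovers `x` exactly (to 1e-12
#' on numeric columns) for every artifact the pipeline produces.
#'
#' @param events,weather,exposure,sdoh,county_ors event / weather / exposure
#'   / covariate / stage-1 output tables as produced by the package.
#' @param path file path.
#' @return the written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name heatvuln_io
NULL

.check_columns <- function(df, required, what, path) {
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file %s lacks column(s): %s", what, path,
                 paste(miss, collapse = ", ")))
  }
}

.check_values <- function(ok, what, column) {
  if (any(!ok)) {
    stop(sprintf("%s: invalid value in column '%s' at row %d", what, column,
                 which(!ok)[1]))
  }
}

#' @rdname heatvuln_io
#' @export
write_events <- function(events, path) {
  out <- events
  out$date <- format(as.Date(out$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatvuln_io
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(icd9 = "character"))
  .check_columns(df, c("patient_id", "date", "icd9", "outcome", "stream",
                       "county_id", "zip_id"), "events", path)
  .check_values(df$stream %in% c("ED", "HSP"), "events", "stream")
  .check_values(df$outcome %in% names(OUTCOME_DEDUP_WINDOWS), "events",
                "outcome")
  df$date <- as.Date(df$date)
  .check_values(!is.na(df$date), "events", "date")
  df
}

#' @rdname heatvuln_io
#' @export
write_weather <- function(weather, path) {
  out <- weather
  out$date <- format(as.Date(out$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatvuln_io
#' @export
read_weather <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("county_id", "date", "tmax_c", "tmean_c", "tmin_c",
                       "rh_pct"), "weather", path)
  df$date <- as.Date(df$date)
  .check_values(!is.na(df$date), "weather", "date")
  .check_values(df$rh_pct >= 0 & df$rh_pct <= 100, "weather", "rh_pct")
  df
}

#' @rdname heatvuln_io
#' @export
write_exposure <- function(exposure, path) {
  out <- exposure
  out$date <- format(as.Date(out$date))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatvuln_io
#' @export
read_exposure <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("county_id", "date", "tmax_c", "tmean_c", "tmin_c",
                       "himax_c"), "exposure", path)
  df$date <- as.Date(df$date)
  .check_values(!is.na(df$date), "exposure", "date")
  .check_values(df$tmin_c <= df$tmean_c & df$tmean_c <= df$tmax_c,
                "exposure", "tmean_c")
  df
}

#' @rdname heatvuln_io
#' @export
write_sdoh <- function(sdoh, path) {
  write.csv(sdoh, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatvuln_io
#' @export
read_sdoh <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, "county_id", "sdoh", path)
  if (ncol(df) < 2) stop("sdoh file has no covariate columns: ", path)
  df
}

#' @rdname heatvuln_io
#' @export
write_county_ors <- function(county_ors, path) {
  write.csv(county_ors, path, row.names = FALSE)
  invisible(path)
}

#' @rdname heatvuln_io
#' @export
read_county_ors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("county_id", "outcome", "stream", "metric", "lag",
                       "beta", "se", "or_value", "n_cases", "aic",
                       "converged"), "county_or", path)
  .check_values(df$or_value > 0, "county_or", "or_value")
  df
}

#' Write a spatial weights matrix as an undirected edge list
#'
#' @param w binary symmetric adjacency matrix with county-id dimnames.
#' @param path output CSV path (columns `i`, `j`; each undirected pair once).
#' @export
write_adjacency <- function(w, path) {
  idx <- which(w != 0 & upper.tri(w), arr.ind = TRUE)
  df <- data.frame(i = rownames(w)[idx[, 1]], j = colnames(w)[idx[, 2]],
                   stringsAsFactors = FALSE)
  write.csv(df[order(df$i, df$j), ], path, row.names = FALSE)
  invisible(path)
}

#' Read a spatial weights matrix from an edge list
#'
#' Accepts either one row per undirected pair or both directions; if both
#' directions appear they must agree (the matrix must be symmetric).
#'
#' @param path edge-list CSV with columns `i`, `j`.
#' @param ids optional full county-id vector (isolated counties included).
#' @return binary symmetric matrix with zero diagonal.
#' @export
read_adjacency <- function(path, ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("i", "j"), "adjacency", path)
  if (any(df$i == df$j)) stop("adjacency edge list contains a self-loop")
  if (is.null(ids)) ids <- sort(unique(c(df$i, df$j)))
  w <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  w[cbind(match(df$i, ids), match(df$j, ids))] <- 1L
  fwd <- paste(df$i, df$j, sep = "\r")
  rev <- paste(df$j, df$i, sep = "\r")
  if (any(fwd %in% rev)) {
    # Both directions listed: the file is a directed matrix and must be
    # symmetric as given.
    if (!identical(w, t(w))) stop("adjacency edge list is asymmetric")
  } else {
    w <- pmax(w, t(w))  # one row per undirected pair
  }
  w
}

#' @rdname heatvuln_io
#' @export
write_stage2 <- function(stage2, path) {
  rows <- lapply(stage2$results, function(r) {
    data.frame(
      outcome = r$outcome, stream = r$stream, model_type = r$model_type,
      variable = c("(Intercept)", r$variables),
      estimate = c(r$intercept, unname(r$estimates)),
      se = c(NA_real_, unname(r$se)), p = c(NA_real_, unname(r$p)),
      rho = r$rho, aic = r$aic, moran_I = r$moran_I, moran_p = r$moran_p,
      ks_p = r$ks_p, stringsAsFactors = FALSE
    )
  })
  write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))), path,
            row.names = FALSE)
  invisible(path)
}
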