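#' Prune collinear covariates by pairwise correlation
#'
#' Greedy multicollinearity filter: while any pair of remaining variables has
#' absolute Pearson correlation above `threshold`, the member of the worst
#' pair with the larger mean absolute correlation against all other remaining
#' variables is removed (ties broken by column order, dropping the later
#' column). An explicit `drop` list overrides the greedy rule, e.g. to
#' reproduce a published 12-variable removal.
#'
#' @param table data.frame of numeric covariates (a `county_id` column, if
#'   present, is ignored).
#' @param threshold absolute correlation above which a pair is collinear
#'   (default 0.7).
#' @param drop optional character vector of variables to remove instead of
#'   the greedy rule.
#' @return list with `kept` and `dropped` variable names (original column
#'   order preserved).
#' @export
correlation_prune <- function(table, threshold = 0.7, drop = NULL) {
  x <- table[setdiff(names(table), "county_id")]
  vars <- names(x)
  if (length(vars) < 2) stop("need at least 2 covariates")
  if (nrow(x) < 3) stop("need at least 3 rows to estimate correlations")
  if (!is.null(drop)) {
    return(list(kept = setdiff(vars, drop), dropped = intersect(vars, drop)))
  }
  sds <- vapply(x, sd, 0)
  if (any(sds == 0)) {
    stop("constant column(s) with undefined correlation: ",
         paste(vars[sds == 0], collapse = ", "))
  }
  cmat <- abs(cor(as.matrix(x)))
  diag(cmat) <- 0
  keep <- vars
  repeat {
    sub <- cmat[keep, keep, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[hit[1]]
    b <- keep[hit[2]]
    mean_abs <- function(v) mean(cmat[v, setdiff(keep, v)])
    victim <- if (mean_abs(a) > mean_abs(b)) {
      a
    } else if (mean_abs(b) > mean_abs(a)) {
      b
    } else {
      keep[max(match(c(a, b), keep))]
    }
    keep <- setdiff(keep, victim)
    if (length(keep) < 2) break
  }
  list(kept = keep, dropped = setdiff(vars, keep))
}

#' Ordinary least squares with Gaussian-likelihood AIC
#'
#' Least squares with an intercept; `AIC = 2(p + 2) - 2 loglik`, counting the
#' intercept, slopes, and error variance. With zero predictors the
#' intercept-only model (mean of `y`) is returned.
#'
#' @param y response vector.
#' @param x predictor data.frame/matrix (no intercept column; may be empty
#'   or `NULL`).
#' @return list of class `ols_fit`: `coefficients`, `se`, `p` (two-sided t),
#'   `residuals`, `fitted`, `aic`, `loglik`, `n`, `df_residual`.
#' @export
ols_fit <- function(y, x = NULL) {
  n <- length(y)
  xm <- stage2_model_matrix(x, n)
  p <- ncol(xm)
  if (n <= p) stop("need n > p + 1 observations")
  qx <- qr(xm)
  if (qx$rank < p) {
    aliased <- colnames(xm)[qx$pivot[(qx$rank + 1):p]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  fitted <- as.numeric(xm %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df_res <- n - p
  sigma2_hat <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(diag(xtx_inv) * sigma2_hat)
  tstat <- beta / se
  pvals <- 2 * pt(-abs(tstat), df_res)
  names(se) <- names(pvals) <- names(beta)
  loglik <- -(n / 2) * (log(2 * pi * rss / n) + 1)
  structure(list(
    coefficients = beta, se = se, p = pvals, residuals = resid,
    fitted = fitted, aic = 2 * (p + 1) - 2 * loglik, loglik = loglik,
    n = n, df_residual = df_res
  ), class = "ols_fit")
}

#' Kolmogorov-Smirnov test of residual normality
#'
#' One-sample KS test of the standardised residuals against the standard
#' normal distribution, with the asymptotic p-value.
#'
#' @param residuals numeric residual vector (length >= 5, non-constant).
#' @return list with `statistic` and `p`.
#' @export
ks_normality <- function(residuals) {
  if (length(residuals) < 5) stop("need at least 5 residuals")
  s <- sd(residuals)
  if (s == 0) stop("zero-variance residuals")
  z <- (residuals - mean(residuals)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm", exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Backward stepwise selection by AIC
#'
#' Starts from the full model and repeatedly deletes the single variable
#' whose removal lowers the AIC the most, stopping when no deletion improves
#' it. Deterministic given the input column ordering (ties keep the earlier
#' candidate).
#'
#' @param y response vector.
#' @param x data.frame of candidate predictors.
#' @param fitter function `(y, x) -> fit` returning at least `$aic`
#'   (default [ols_fit]; a spatial-lag fitter can be passed instead).
#' @return list: `selected` (character), `fit` (final fitted model), `trace`
#'   (data.frame of each step's removal and AIC).
#' @export
backward_stepwise_aic <- function(y, x, fitter = ols_fit) {
  current <- names(x)
  fit <- fitter(y, x[current])
  trace <- data.frame(removed = "<full>", aic = fit$aic,
                      stringsAsFactors = FALSE)
  while (length(current) > 0) {
    cand_aic <- vapply(current, function(v) {
      fitter(y, x[setdiff(current, v)])$aic
    }, 0)
    best <- which.min(cand_aic)
    if (cand_aic[best] >= fit$aic) break
    removed <- current[best]
    current <- setdiff(current, removed)
    fit <- fitter(y, x[current])
    trace <- rbind(trace, data.frame(removed = removed, aic = fit$aic,
                                     stringsAsFactors = FALSE))
  }
  list(selected = current, fit = fit, trace = trace)
}

#' Choose between the aspatial and spatial lag model
#'
#' Fits the aspatial linear model, tests its residuals for normality (KS)
#' and spatial autocorrelation (Moran's I Monte Carlo p), fits the
#' maximum-likelihood spatial lag model on the same predictors, and selects
#' the spatial lag model iff residual autocorrelation is detected
#' (`mc_p <= alpha`) or the spatial model has strictly lower AIC; otherwise
#' the aspatial model is kept. For the spatial model the reported
#' per-variable estimates are the global average total impacts, with
#' p-values carried from the coefficient tests.
#'
#' @param y response vector (county odds ratios).
#' @param x data.frame of selected predictors.
#' @param w spatial weights matrix aligned to `y`.
#' @param alpha significance level for residual autocorrelation (default
#'   0.05).
#' @param n_permutations Moran permutation count (default 999).
#' @param seed optional seed for the Moran permutations.
#' @return list of class `stage2_model`: `model_type` ("MLR" or
#'   "spatial_lag"), `variables`, `estimates` (per variable; total impacts
#'   under the spatial model), `se`, `p`, `intercept`, `rho`, `rho_p`,
#'   `aic`, `aic_mlr`, `aic_spatial`, `moran_I`, `moran_p`, `ks_stat`,
#'   `ks_p`, `fit`.
#' @export
choose_model <- function(y, x, w, alpha = 0.05, n_permutations = 999,
                         seed = NULL) {
  mlr <- ols_fit(y, x)
  ks <- ks_normality(mlr$residuals)
  mi <- morans_I(mlr$residuals, w, n_permutations, seed = seed)
  slm <- spatial_lag_fit(y, x, w)
  spatial <- (mi$mc_p <= alpha) || (slm$aic < mlr$aic)

  vars <- setdiff(names(mlr$coefficients), "(Intercept)")
  if (spatial) {
    est <- total_impacts(slm$coefficients[vars], slm$rho, w)
    res <- list(
      model_type = "spatial_lag", variables = vars, estimates = est,
      se = slm$se[vars], p = slm$p[vars],
      intercept = unname(slm$coefficients["(Intercept)"]),
      rho = slm$rho, rho_p = slm$rho_p, aic = slm$aic, fit = slm
    )
  } else {
    res <- list(
      model_type = "MLR", variables = vars,
      estimates = mlr$coefficients[vars], se = mlr$se[vars], p = mlr$p[vars],
      intercept = unname(mlr$coefficients["(Intercept)"]),
      rho = NA_real_, rho_p = NA_real_, aic = mlr$aic, fit = mlr
    )
  }
  res$aic_mlr <- mlr$aic
  res$aic_spatial <- slm$aic
  res$moran_I <- mi$I
  res$moran_p <- mi$mc_p
  res$ks_stat <- ks$statistic
  res$ks_p <- ks$p
  class(res) <- "stage2_model"
  res
}

#' @export
print.stage2_model <- function(x, ...) {
  cat(sprintf("<stage2_model> %s  AIC=%.2f (MLR %.2f / spatial %.2f)\n",
              x$model_type, x$aic, x$aic_mlr, x$aic_spatial))
  cat(sprintf("  Moran's I on MLR residuals: %.4f (mc p=%.3f); KS p=%.3f\n",
              x$moran_I, x$moran_p, x$ks_p))
  if (!is.na(x$rho)) cat(sprintf("  rho = %.4f (p=%.3g)\n", x$rho, x$rho_p))
  print(data.frame(estimate = x$estimates, se = x$se, p = x$p))
  invisible(x)
}

#' Stage 2: relate county odds ratios to SDOH
#'
#' For each outcome-by-stream cell with enough modelled counties, runs the
#' full second stage: correlation pruning of the covariates, backward
#' stepwise AIC selection (under the aspatial fitter by default), and the
#' aspatial-versus-spatial-lag model choice with Moran's I and KS
#' diagnostics. Counties absent from the odds-ratio table (e.g. under the
#' 30-case rule) are excluded from both response and design; cells with
#' fewer than `max(10, p + 5)` counties are skipped with a reason.
#'
#' @param county_ors data.frame from [estimate_county_ors()].
#' @param sdoh county covariate table (`county_id` plus numeric columns).
#' @param w spatial weights matrix with county ids as dimnames; defines the
#'   canonical county ordering.
#' @param threshold correlation-pruning threshold (default 0.7).
#' @param drop optional explicit pruning list (see [correlation_prune()]).
#' @param alpha significance level for diagnostics (default 0.05).
#' @param n_permutations Moran permutation count (default 999).
#' @param seed optional seed for Moran permutations.
#' @param use_log_or regress the log odds ratio instead of the odds ratio
#'   (default `FALSE`: the odds ratio itself is the response).
#' @param stepwise_spatial run the stepwise search under the spatial-lag
#'   fitter instead of OLS (default `FALSE`).
#' @return list of class `stage2_analysis`: `results` (named list of
#'   `stage2_model` per "outcome/stream" cell, each with `outcome`, `stream`,
#'   `counties`, `pruned` attached), `skipped` (data.frame with reasons).
#' @export
stage2_analysis <- function(county_ors, sdoh, w, threshold = 0.7, drop = NULL,
                            alpha = 0.05, n_permutations = 999, seed = NULL,
                            use_log_or = FALSE, stepwise_spatial = FALSE) {
  if (is.null(dimnames(w))) stop("weights matrix must carry county ids as dimnames")
  unmatched <- setdiff(county_ors$county_id, sdoh$county_id)
  if (length(unmatched)) {
    stop("counties with ORs but no SDOH row: ", paste(unmatched, collapse = ", "))
  }
  unmatched_w <- setdiff(county_ors$county_id, rownames(w))
  if (length(unmatched_w)) {
    stop("counties with ORs but absent from weights: ",
         paste(unmatched_w, collapse = ", "))
  }

  cells <- unique(county_ors[c("outcome", "stream")])
  results <- list()
  skipped <- data.frame(outcome = character(), stream = character(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    oc <- cells$outcome[i]
    strm <- cells$stream[i]
    sub <- county_ors[county_ors$outcome == oc & county_ors$stream == strm, ]
    counties <- intersect(rownames(w), sub$county_id)  # canonical W order
    ord <- match(counties, sub$county_id)
    y <- if (use_log_or) sub$beta[ord] else sub$or_value[ord]
    xall <- sdoh[match(counties, sdoh$county_id),
                 setdiff(names(sdoh), "county_id"), drop = FALSE]
    if (anyNA(xall)) stop("missing SDOH values among modelled counties")

    pr <- correlation_prune(xall, threshold, drop)
    p_cand <- length(pr$kept)
    min_n <- max(10, p_cand + 5)
    if (length(counties) < min_n) {
      skipped <- rbind(skipped, data.frame(
        outcome = oc, stream = strm,
        reason = sprintf("only %d counties with ORs (< %d required)",
                         length(counties), min_n),
        stringsAsFactors = FALSE
      ))
      next
    }
    w_sub <- w[counties, counties, drop = FALSE]
    fitter <- if (stepwise_spatial) {
      function(y, x) spatial_lag_fit(y, x, w_sub)
    } else {
      ols_fit
    }
    step <- backward_stepwise_aic(y, xall[pr$kept], fitter)
    model <- choose_model(y, xall[step$selected], w_sub,
                          alpha, n_permutations, seed)
    model$outcome <- oc
    model$stream <- strm
    model$counties <- counties
    model$pruned <- pr$dropped
    model$stepwise_trace <- step$trace
    results[[paste(oc, strm, sep = "/")]] <- model
  }
  structure(list(results = results, skipped = skipped),
            class = "stage2_analysis")
}

#' @export
print.stage2_analysis <- function(x, ...) {
  cat(sprintf("<stage2_analysis> %d modelled cell(s), %d skipped\n",
              length(x$results), nrow(x$skipped)))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %-28s %-11s AIC=%.2f vars: %s\n", nm, r$model_type, r$aic,
                paste(r$variables, collapse = ", ")))
  }
  if (nrow(x$skipped)) {
    for (i in seq_len(nrow(x$skipped))) {
      cat(sprintf("  skipped %s/%s: %s\n", x$skipped$outcome[i],
                  x$skipped$stream[i], x$skipped$reason[i]))
    }
  }
  invisible(x)
}
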