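#' Global Moran's I with Monte Carlo inference
#'
#' Computes `I = (n/S0) * (sum_ij w_ij z_i z_j) / (sum_i z_i^2)` with
#' mean-centred values `z` and `S0 = sum_ij w_ij`, using the supplied binary
#' (not row-standardised) weights, and a permutation p-value: values are
#' randomly reassigned to locations `n_permutations` times and the two-sided
#' p-value is twice the smaller tail of
#' `(1 + #{permuted I at least as extreme}) / (1 + n_permutations)`.
#'
#' @param values numeric vector (non-constant, length >= 4).
#' @param w square spatial weights matrix with at least one nonzero entry.
#' @param n_permutations number of Monte Carlo permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list: `I`, `expected_I` (= -1/(n-1)), `mc_p`, `n_permutations`.
#' @export
morans_I <- function(values, w, n_permutations = 999, seed = NULL) {
  n <- length(values)
  if (n < 4) stop("Moran's I needs at least 4 observations")
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n) {
    stop("weights must be an n x n matrix matching `values`")
  }
  s0 <- sum(w)
  if (s0 == 0) stop("weights matrix has no nonzero entries")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("values are constant; Moran's I undefined")
  obs <- (n / s0) * as.numeric(crossprod(z, w %*% z)) / denom

  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    zp <- z[sample.int(n)]
    perm[b] <- (n / s0) * as.numeric(crossprod(zp, w %*% zp)) / denom
  }
  p_up <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  p_lo <- (1 + sum(perm <= obs)) / (1 + n_permutations)
  list(
    I = obs, expected_I = -1 / (n - 1),
    mc_p = min(1, 2 * min(p_up, p_lo)),
    n_permutations = n_permutations
  )
}

# Model matrix with intercept from a covariate data.frame/matrix (possibly
# zero predictors).
stage2_model_matrix <- function(x, n) {
  if (is.null(x) || NCOL(x) == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    xm <- as.matrix(x)
    cbind(`(Intercept)` = 1, xm)
  }
}

#' Maximum-likelihood spatial lag model
#'
#' Fits `y = rho * W y + X beta + eps` by maximising the concentrated
#' log-likelihood `l(rho) = sum_i log(1 - rho * lambda_i) -
#' (n/2) log(SSE(rho)/n)` over the feasible interval
#' `(1/lambda_min, 1/lambda_max)` defined by the extreme eigenvalues of the
#' (symmetric, binary, not row-standardised) weights matrix; the
#' log-determinant uses the precomputed eigenvalues. Coefficients come from
#' least squares on the spatially filtered response at the optimum, and
#' asymptotic standard errors from the inverse information matrix in
#' `(beta, rho, sigma^2)`. A zero weights matrix leaves rho unidentified:
#' the fit collapses to OLS with `rho = 0` and is flagged.
#'
#' @param y response vector.
#' @param x predictor data.frame/matrix (no intercept column; may be empty).
#' @param w symmetric binary spatial weights matrix.
#' @return list of class `spatial_lag_fit`: `rho`, `rho_se`, `rho_p`,
#'   `coefficients`, `se`, `p` (named, intercept first), `loglik`, `aic`,
#'   `sigma2`, `residuals`, `rho_interval`, `converged`, `rho_identified`,
#'   `n`.
#' @export
spatial_lag_fit <- function(y, x, w) {
  n <- length(y)
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n) {
    stop("weights must be an n x n matrix matching `y`")
  }
  if (max(abs(w - t(w))) > 1e-12) stop("weights matrix must be symmetric")
  xm <- stage2_model_matrix(x, n)
  p <- ncol(xm)
  if (n <= p + 2) stop("need n > p + 2 observations for the spatial lag model")

  if (all(w == 0)) {
    fit <- ols_fit(y, x)
    return(structure(list(
      rho = 0, rho_se = NA_real_, rho_p = NA_real_,
      coefficients = fit$coefficients, se = fit$se, p = fit$p,
      loglik = fit$loglik, aic = fit$aic, sigma2 = sum(fit$residuals^2) / n,
      residuals = fit$residuals, rho_interval = c(0, 0),
      converged = TRUE, rho_identified = FALSE, n = n
    ), class = "spatial_lag_fit"))
  }

  lambda <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  lo <- 1 / min(lambda)
  hi <- 1 / max(lambda)
  wy <- as.numeric(w %*% y)
  qx <- qr(xm)
  sse_of <- function(rho) {
    r <- qr.resid(qx, y - rho * wy)
    sum(r^2)
  }
  cll <- function(rho) sum(log(1 - rho * lambda)) - (n / 2) * log(sse_of(rho) / n)
  eps <- 1e-6 * (hi - lo)
  opt <- optimize(cll, interval = c(lo + eps, hi - eps), maximum = TRUE,
                  tol = 1e-10)
  rho <- opt$maximum
  converged <- (rho - lo) > 1e-4 * (hi - lo) && (hi - rho) > 1e-4 * (hi - lo)

  ay <- y - rho * wy
  beta <- qr.coef(qx, ay)
  resid <- as.numeric(ay - xm %*% beta)
  sigma2 <- sum(resid^2) / n
  ll <- -(n / 2) * (log(2 * pi * sigma2) + 1) + sum(log(1 - rho * lambda))
  aic <- 2 * (p + 2) - 2 * ll

  # Information matrix in (beta, rho, sigma2); C = W (I - rho W)^{-1}.
  a_inv <- solve(diag(n) - rho * w)
  cmat <- w %*% a_inv
  cxb <- as.numeric(cmat %*% (xm %*% beta))
  info <- matrix(0, p + 2, p + 2)
  info[1:p, 1:p] <- crossprod(xm) / sigma2
  info[1:p, p + 1] <- info[p + 1, 1:p] <- crossprod(xm, cxb) / sigma2
  info[p + 1, p + 1] <- sum(cmat * t(cmat)) + sum(cmat * cmat) +
    sum(cxb^2) / sigma2
  info[p + 1, p + 2] <- info[p + 2, p + 1] <- sum(diag(cmat)) / sigma2
  info[p + 2, p + 2] <- n / (2 * sigma2^2)
  vcov_all <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, p + 2, p + 2)
  })
  se <- sqrt(pmax(0, diag(vcov_all)[1:p]))
  rho_se <- sqrt(max(0, diag(vcov_all)[p + 1]))
  zstat <- beta / se
  pvals <- 2 * pnorm(-abs(zstat))
  rho_p <- 2 * pnorm(-abs(rho / rho_se))
  names(se) <- names(pvals) <- names(beta)

  structure(list(
    rho = rho, rho_se = rho_se, rho_p = rho_p,
    coefficients = beta, se = se, p = pvals,
    loglik = ll, aic = aic, sigma2 = sigma2, residuals = resid,
    rho_interval = c(lo, hi), converged = converged, rho_identified = TRUE,
    n = n
  ), class = "spatial_lag_fit")
}

#' @export
print.spatial_lag_fit <- function(x, ...) {
  cat(sprintf("<spatial_lag_fit> n=%d rho=%.4f (se %.4f)  AIC=%.2f\n",
              x$n, x$rho, x$rho_se, x$aic))
  print(data.frame(estimate = x$coefficients, se = x$se, p = x$p))
  invisible(x)
}

#' Global average total impacts of a spatial lag model
#'
#' The average total (direct plus spillover) effect of a one-unit change in
#' predictor k is `ATI_k = n^{-1} 1' (I - rho W)^{-1} 1 * beta_k`. P-values
#' are carried over from the coefficient tests.
#'
#' @param beta named coefficient vector (slopes only).
#' @param rho spatial autoregressive parameter.
#' @param w spatial weights matrix used in the fit.
#' @return named vector of average total impacts.
#' @export
total_impacts <- function(beta, rho, w) {
  n <- nrow(w)
  a <- diag(n) - rho * w
  mult <- tryCatch(mean(solve(a, rep(1, n))),
                   error = function(e) stop("(I - rho W) is singular"))
  beta * mult
}
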