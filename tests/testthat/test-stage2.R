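test_that("correlation pruning removes exactly the collinear structure", {
  set.seed(8)
  n <- 100
  base <- rnorm(n)
  tab <- data.frame(
    a = rnorm(n), b = rnorm(n),
    c1 = base + rnorm(n, 0, 0.3), c2 = base + rnorm(n, 0, 0.3),
    c3 = base + rnorm(n, 0, 0.3), d = rnorm(n)
  )
  # planted r ~ 0.9 block of 3: after pruning no surviving pair exceeds 0.7,
  # verified by full recomputation on the survivor set
  pr <- correlation_prune(tab, 0.7)
  cm <- abs(cor(as.matrix(tab[pr$kept])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.7)
  expect_true(all(c("a", "b", "d") %in% pr$kept))

  # all pairs below threshold: nothing dropped
  ind <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(correlation_prune(ind, 0.7)$dropped, character(0))

  # duplicated column: exactly one of the pair dropped
  dup <- data.frame(a = base, b = base, c = rnorm(n))
  prd <- correlation_prune(dup, 0.7)
  expect_equal(length(prd$dropped), 1)
  expect_true(prd$dropped %in% c("a", "b"))

  # explicit override wins
  ov <- correlation_prune(tab, 0.7, drop = c("c1", "d"))
  expect_equal(ov$dropped, c("c1", "d"))
  expect_equal(ov$kept, c("a", "b", "c2", "c3"))

  cst <- data.frame(a = rnorm(n), b = rep(1, n))
  expect_error(correlation_prune(cst), "constant.*b")
})

test_that("OLS matches the pseudo-inverse oracle and stats::lm", {
  set.seed(7)
  n <- 50
  x <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 1 + 2 * x$x1 - 0.5 * x$x3 + rnorm(n)
  fit <- ols_fit(y, x)
  xm <- cbind(1, as.matrix(x))
  oracle <- solve(t(xm) %*% xm) %*% t(xm) %*% y
  expect_equal(unname(fit$coefficients), as.numeric(oracle), tolerance = 1e-8)

  lmfit <- lm(y ~ x1 + x2 + x3, data = x)
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(lmfit)))),
               tolerance = 1e-10)
  expect_equal(fit$aic, AIC(lmfit), tolerance = 1e-10)
  expect_equal(unname(fit$p),
               unname(summary(lmfit)$coefficients[, 4]), tolerance = 1e-10)

  # exact linear response: zero residuals
  y0 <- 3 + x$x1 - x$x2
  expect_lt(max(abs(ols_fit(y0, x)$residuals)), 1e-10)

  # empty design: intercept-only model returns the mean
  f0 <- ols_fit(y, NULL)
  expect_equal(unname(f0$coefficients), mean(y))

  # rank deficiency reported with the aliased column
  xr <- transform(x, x4 = x1 + x2)
  expect_error(ols_fit(y, xr), "aliased.*x4")
})

test_that("KS normality test is definitional and calibrated", {
  # definitional check on a 5-point sample
  z <- c(-1.2, -0.4, 0.1, 0.7, 1.5)
  zs <- (z - mean(z)) / sd(z)
  f <- pnorm(sort(zs))
  i <- 1:5
  d_hand <- max(pmax(abs(i / 5 - f), abs(f - (i - 1) / 5)))
  expect_equal(ks_normality(z)$statistic, d_hand, tolerance = 1e-12)

  set.seed(3)
  expect_gt(ks_normality(rnorm(1000))$p, 0.01)     # null calibration
  expect_lt(ks_normality(rcauchy(1000))$p, 0.01)   # gross violation
  expect_error(ks_normality(rep(2, 10)), "zero-variance")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("backward stepwise AIC removes noise and is locally optimal", {
  set.seed(11)
  n <- 200
  x <- data.frame(signal1 = rnorm(n), signal2 = rnorm(n), noise = rnorm(n))
  y <- 1 + 1.5 * x$signal1 - 2 * x$signal2 + rnorm(n)
  st <- backward_stepwise_aic(y, x)
  expect_equal(sort(st$selected), c("signal1", "signal2"))
  # oracle comparison of the two candidate models
  expect_lt(ols_fit(y, x[c("signal1", "signal2")])$aic, ols_fit(y, x)$aic)

  # no deletion improves at step 1 -> full model returned
  y2 <- 1 + x$signal1 + x$signal2 + x$noise + rnorm(n, 0, 0.1)
  st2 <- backward_stepwise_aic(y2, x)
  expect_equal(st2$selected, names(x))

  # p = 4: final AIC >= exhaustive best-subset AIC; no single deletion from
  # the final set lowers AIC
  set.seed(12)
  x4 <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60), d = rnorm(60))
  y4 <- 0.5 * x4$a - x4$c + rnorm(60)
  st4 <- backward_stepwise_aic(y4, x4)
  subsets <- unlist(lapply(0:4, function(k) {
    combn(names(x4), k, simplify = FALSE)
  }), recursive = FALSE)
  best_subset_aic <- min(vapply(subsets, function(s) ols_fit(y4, x4[s])$aic, 0))
  expect_gte(st4$fit$aic + 1e-12, best_subset_aic)
  for (v in st4$selected) {
    expect_gte(ols_fit(y4, x4[setdiff(st4$selected, v)])$aic, st4$fit$aic)
  }
})

test_that("model choice follows the residual-autocorrelation / AIC rule", {
  w <- generate_adjacency(7, 7)
  n <- 49
  # independent-noise data: MLR chosen in the large majority of replicates
  # (the AIC branch alone triggers at roughly the chi-square(1) > 2 rate)
  set.seed(21)
  datasets <- lapply(1:100, function(b) {
    x <- data.frame(x1 = rnorm(n))
    list(x = x, y = 1 + 0.5 * x$x1 + rnorm(n, 0, 0.2))
  })
  chose_mlr <- vapply(seq_along(datasets), function(b) {
    d <- datasets[[b]]
    choose_model(d$y, d$x, w, n_permutations = 199, seed = b)$model_type ==
      "MLR"
  }, NA)
  expect_gt(mean(chose_mlr), 0.6)

  # strongly lag-generated data: spatial model chosen
  set.seed(22)
  x <- data.frame(x1 = rnorm(n))
  lambda_max <- max(eigen(w, symmetric = TRUE, only.values = TRUE)$values)
  rho_big <- 0.8 / lambda_max
  y <- as.numeric(solve(diag(n) - rho_big * w,
                        1 + 0.5 * x$x1 + rnorm(n, 0, 0.2)))
  pick <- choose_model(y, x, w, n_permutations = 199, seed = 1)
  expect_equal(pick$model_type, "spatial_lag")
  expect_equal(unname(pick$estimates),
               unname(total_impacts(pick$fit$coefficients["x1"], pick$rho, w)))
})

test_that("stage 2 skips thin cells and aligns counties", {
  cfg <- sim_config(n_counties = 16, n_rows = 4, n_cols = 4, years = 2009,
                    seed = 9)
  sdoh <- generate_sdoh(cfg)
  w <- generate_adjacency(4, 4)
  ors <- data.frame(
    county_id = county_ids(16)[1:5], outcome = "dehydration", stream = "ED",
    metric = "tmean", lag = 0, beta = rnorm(5, 0.03, 0.01), se = 0.01,
    or_value = exp(rnorm(5, 0.03, 0.01)), n_cases = 100, aic = 100,
    converged = TRUE, stringsAsFactors = FALSE
  )
  res <- stage2_analysis(ors, sdoh, w, n_permutations = 99)
  expect_equal(length(res$results), 0)
  expect_equal(nrow(res$skipped), 1)
  expect_match(res$skipped$reason, "only 5 counties")

  bad <- transform(ors, county_id = paste0("X", 1:5))
  expect_error(stage2_analysis(bad, sdoh, w), "no SDOH row")
})

test_that("stage 2 output is invariant to county row order", {
  cfg <- sim_config(n_counties = 36, n_rows = 6, n_cols = 6, years = 2009,
                    seed = 14)
  sdoh <- generate_sdoh(cfg)
  w <- generate_adjacency(6, 6)
  set.seed(15)
  ors <- data.frame(
    county_id = county_ids(36), outcome = "dehydration", stream = "ED",
    metric = "tmean", lag = 0, beta = 0, se = 0.01, or_value = 0, n_cases = 100,
    aic = 100, converged = TRUE, stringsAsFactors = FALSE
  )
  ors$or_value <- exp(1 + 0.004 * sdoh$pct_over_65 + rnorm(36, 0, 0.01))
  r1 <- stage2_analysis(ors, sdoh, w, n_permutations = 99, seed = 4)
  r2 <- stage2_analysis(ors[rev(seq_len(36)), ], sdoh, w,
                        n_permutations = 99, seed = 4)
  expect_equal(r1$results[[1]]$estimates, r2$results[[1]]$estimates)
  expect_equal(r1$results[[1]]$model_type, r2$results[[1]]$model_type)
  expect_equal(r1$results[[1]]$aic, r2$results[[1]]$aic)
})
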