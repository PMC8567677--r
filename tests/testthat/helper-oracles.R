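# Independent oracles and fixture builders used across the test files.
# Each oracle is a deliberately naive reimplementation (literal transcription,
# brute force, or closed form) kept separate from the package code paths it
# checks.

# Literal transcription of the nine-coefficient Heat Index regression
# polynomial (T in deg F, R in percent), no adjustments.
oracle_heat_index_poly <- function(t, r) {
  -42.379 +
    2.049015 * t +
    10.143331 * r +
    -0.224755 * t * r +
    -6.83783e-3 * t^2 +
    -5.481717e-2 * r^2 +
    1.22874e-3 * t^2 * r +
    8.5282e-4 * t * r^2 +
    -1.99e-6 * t^2 * r^2
}

# Literal NWS low-humidity adjustment, subtracted from the polynomial.
oracle_low_rh_adjustment <- function(t, r) {
  ((13 - r) / 4) * sqrt((17 - abs(t - 95)) / 17)
}

# Naive per-stratum conditional logistic log-likelihood (loops, no
# centering/overflow tricks).
oracle_clogit_loglik <- function(beta, x) {
  ll <- 0
  for (i in seq_len(nrow(x))) {
    ll <- ll + beta * x[i, 1] - log(sum(exp(beta * x[i, ])))
  }
  ll
}

# Dense grid maximisation of the conditional likelihood over [lo, hi].
oracle_clogit_grid <- function(x, lo = -2, hi = 2, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, oracle_clogit_loglik, 0, x = x)
  grid[which.max(ll)]
}

# O(n^2) double-sum Moran's I.
oracle_moran <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Simulate matched 1:3 strata directly from the conditional model: exposures
# are N(0, sd), the case slot is drawn with softmax(beta * x) probability and
# moved to column 1.
make_strata <- function(n, beta, sd = 1, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(4 * n, sd = sd), n, 4)
  for (i in seq_len(n)) {
    p <- exp(beta * x[i, ])
    k <- sample(4, 1, prob = p / sum(p))
    x[i, ] <- x[i, c(k, setdiff(1:4, k))]
  }
  x
}

# Small deterministic daily weather table for exposure tests.
make_weather_fixture <- function(n_counties = 2, years = 2009,
                                 seed = 42) {
  cfg <- sim_config(
    n_counties = n_counties, n_rows = 1, n_cols = n_counties,
    years = years, baseline_rate = 1, gamma = c(), gamma0 = 0,
    beta_noise_sd = 0, dup_frac = 0, seed = seed
  )
  generate_weather(cfg)
}
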