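# Shared fixture builders for the test suite. Everything is generated in
# code; no fixture files.

# One survey row in SI units (the worked hand example used across tests).
example_survey <- function(year = 2000, n = 100, x = 1e5, y = 250,
                           area = 2e9) {
  tibble::tibble(year = year, n = n, x = x, y = y, area = area)
}

# Random valid projection-matrix parameter sets.
random_matrix_params <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      F_a = runif(n, 0.01, 1),
      S_n = runif(n, 0.05, 1),
      S_j = runif(n, 0.05, 1),
      S_a = runif(n, 0, 0.99)
    )
  })
}

# Perron-root oracle: largest real root of the characteristic cubic
# lambda^3 - S_a lambda^2 - F_a S_n S_j = 0, via polyroot().
cubic_perron_oracle <- function(F_a, S_n, S_j, S_a) {
  roots <- polyroot(c(-F_a * S_n * S_j, 0, -S_a, 1))
  real <- Re(roots[abs(Im(roots)) < 1e-8])
  max(real)
}

# Project a known matrix from its stable age distribution and return the
# total (both-sex) abundance series it generates.
series_from_matrix <- function(m, years, N0 = 5000, start_year = 2000L) {
  lam <- guanacopop::dominant_eigenvalue(m)
  v <- Re(eigen(m)$vectors[, 1L])
  v <- abs(v) / sum(abs(v)) * N0 / 2
  N <- numeric(years)
  for (t in seq_len(years)) {
    N[t] <- 2 * sum(v)
    v <- as.vector(m %*% v)
  }
  list(series = tibble::tibble(year = seq(start_year, length.out = years),
                               N_hat = N),
       lambda = lam)
}

# Small complete covariate table for regression tests: known coefficients,
# independent climate columns.
toy_covariate_series <- function(years = 20L, seed = 1L, start_year = 2000L) {
  withr::with_seed(seed, {
    tibble::tibble(
      year = seq(start_year, length.out = years),
      precip = rnorm(years, 300, 60),
      winter_temp = rnorm(years, 2.2, 1.5),
      sheep = seq(25000, 40000, length.out = years)
    )
  })
}
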