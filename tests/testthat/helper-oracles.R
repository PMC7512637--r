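# Brute-force quantile oracle: smallest y with F(y) >= tau, found by direct
# minimum search over a cdf grid (the cdf itself is the closed form
# 1 - q^((y+1)^beta)). Independent of the quantile formula under test.
quantile_scan <- function(tau, q, beta) {
  ymax <- 16L
  cdf_at <- function(y) -expm1((y + 1)^beta * log(q))
  while (cdf_at(ymax) < max(tau)) ymax <- ymax * 2L
  F <- cdf_at(0:ymax)
  # 1e-12 slack so float noise in the cdf grid cannot shift an exact
  # boundary (where F(y) equals tau analytically) to the next integer
  vapply(tau, function(t) which(F >= t - 1e-12)[1L] - 1L, 0L)
}

# direct truncated series for the moments, written independently of
# dw_moments' blocked accumulation
moments_scan <- function(q, beta, terms = 5000L) {
  y <- seq_len(terms)
  t1 <- q^(y^beta)
  list(mean = sum(t1), var = 2 * sum(y * t1) - sum(t1) - sum(t1)^2)
}

# one simulated dataset from the regression model used across the studies
sim_reg_data <- function(n, alpha = c(0.5, 0.4, -0.3), beta = 2.1) {
  d <- simulate_covariates(n)
  X <- cbind("(Intercept)" = 1, as.matrix(d))
  y <- simulate_dw_counts(X, alpha, beta)
  list(d = d, X = X, y = y)
}
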