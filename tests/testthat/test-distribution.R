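test_that("pmf and cdf match their closed forms and support boundaries", {
  expect_equal(ddw(0, q = 0.6, beta = 3), 0.4)        # f(0) = 1 - q
  expect_equal(ddw(-1, q = 0.6, beta = 3), 0)
  expect_equal(ddw(1, q = 0.5, beta = 1), 0.25)       # geometric p = 0.5
  expect_equal(ddw(1.5, q = 0.5, beta = 1), 0)        # non-integer: no mass

  expect_equal(pdw(0, q = 0.6, beta = 2), 0.4)
  expect_equal(pdw(0, q = 0.6, beta = 7), 0.4)        # F(0) free of beta
  expect_equal(pdw(-1, q = 0.6, beta = 2), 0)

  y <- 0:4000
  F <- pdw(y, q = 0.9, beta = 0.5)
  expect_true(all(diff(F) >= 0))
  expect_gt(F[length(F)], 0.99)

  expect_error(ddw(1, q = 1.2, beta = 1), "q")
  expect_error(pdw(1, q = 0.5, beta = -1), "beta")
})

test_that("pmf normalises over the support for a parameter grid", {
  for (q in c(0.1, 0.5, 0.9)) {
    for (beta in c(0.5, 1, 2, 4)) {
      ymax <- quantile_scan(1 - 1e-10, q, beta)
      expect_equal(sum(ddw(0:ymax, q = q, beta = beta)), 1, tolerance = 1e-8)
    }
  }
})

test_that("beta = 1 is geometric and beta = 2 is discrete Rayleigh", {
  y <- 0:50
  for (q in c(0.2, 0.5, 0.8)) {
    expect_equal(ddw(y, q = q, beta = 1), dgeom(y, prob = 1 - q),
                 tolerance = 1e-14)
    expect_equal(pdw(y, q = q, beta = 2), 1 - q^((y + 1)^2),
                 tolerance = 1e-14)
  }
})

test_that("quantile function agrees with a brute-force cdf scan", {
  expect_identical(qdw(0.5, q = 0.5, beta = 1), 0)
  expect_identical(qdw(0.3, q = 0.5, beta = 2), 0)   # tau < 1 - q branch
  expect_identical(qdw(0.5, q = 0.9, beta = 2), 2)
  # tau exactly at 1 - q: F(0) = tau, so the quantile is 0
  expect_identical(qdw(0.4, q = 0.6, beta = 3), 0)
  expect_error(qdw(0, q = 0.5, beta = 1), "probabilities")
  expect_error(qdw(1, q = 0.5, beta = 1), "probabilities")

  taus <- seq(0.05, 0.95, by = 0.05)
  for (q in c(0.2, 0.6, 0.9)) {
    for (beta in c(0.5, 1, 2.1, 4)) {
      expect_identical(qdw(taus, q = q, beta = beta),
                       as.numeric(quantile_scan(taus, q, beta)))
    }
  }
})

test_that("quantiles are coherent with the cdf", {
  taus <- seq(0.05, 0.95, by = 0.09)
  for (q in c(0.3, 0.7)) {
    for (beta in c(0.8, 1.5, 3)) {
      Q <- qdw(taus, q = q, beta = beta)
      expect_true(all(pdw(Q, q = q, beta = beta) >= taus))
      above0 <- Q > 0
      expect_true(all(pdw(Q[above0] - 1, q = q, beta = beta) < taus[above0]))
    }
  }
})

test_that("moment series matches closed forms and a direct truncated sum", {
  expect_equal(dw_mean(0.5, 1), 1, tolerance = 1e-9)      # geometric q/(1-q)
  expect_equal(dw_var(0.5, 1), 2, tolerance = 1e-9)       # q/(1-q)^2
  m <- moments_scan(0.6, 2)
  expect_equal(dw_mean(0.6, 2), m$mean, tolerance = 1e-10)
  expect_equal(dw_var(0.6, 2), m$var, tolerance = 1e-10)
  # Bernoulli limit: mean -> q, variance -> q(1-q)
  expect_equal(dw_mean(0.6, 50), 0.6, tolerance = 1e-6)
  expect_equal(dw_var(0.6, 50), 0.24, tolerance = 1e-6)
  # geometric is overdispersed for any q
  expect_gt(dw_var(0.7, 1), dw_mean(0.7, 1))
  # heavy tails (series far beyond the exact-summation cap) are completed
  # analytically: the result must not depend on where the tail takes over
  m_a <- dw_moments(0.9, 0.25, max_terms = 1e5)
  m_b <- dw_moments(0.9, 0.25, max_terms = 1e6)
  expect_true(m_a$converged && m_b$converged)
  expect_equal(m_a$mean, m_b$mean, tolerance = 1e-8)
  expect_equal(m_a$var, m_b$var, tolerance = 1e-8)
  # and agree with the geometric closed form when the tail is geometric
  expect_equal(dw_moments(0.999, 1, max_terms = 100)$mean, 0.999 / 0.001,
               tolerance = 1e-6)
})

test_that("random draws reproduce the moments and the Bernoulli limit", {
  set.seed(101)
  y <- rdw(1e5, q = 0.5, beta = 1)
  se_mean <- sqrt(dw_var(0.5, 1) / 1e5)
  expect_lt(abs(mean(y) - dw_mean(0.5, 1)), 4 * se_mean)
  expect_lt(abs(var(y) - dw_var(0.5, 1)) / dw_var(0.5, 1), 0.05)

  yb <- rdw(1e5, q = 0.6, beta = 10)
  expect_true(all(yb %in% c(0, 1)))
  expect_lt(abs(mean(yb) - 0.6), 4 * sqrt(0.24 / 1e5))

  expect_length(rdw(1, q = 0.3, beta = 2), 1)
  set.seed(7); a <- rdw(100, 0.7, 2.1)
  set.seed(7); b <- rdw(100, 0.7, 2.1)
  expect_identical(a, b)
})

test_that("log-likelihood is the sum of log masses, computed stably", {
  expect_equal(dw_loglik(0, q = 0.6, beta = 2), log(0.4))
  expect_equal(dw_loglik(c(0, 1), q = 0.5, beta = 1), log(0.5) + log(0.25))
  set.seed(3)
  y <- rdw(50, 0.8, 1.5)
  expect_equal(dw_loglik(y, q = 0.8, beta = 1.5),
               sum(log(ddw(y, q = 0.8, beta = 1.5))))
  # large counts / long tails stay finite where the linear-space difference
  # of the two cdf terms would cancel to zero
  expect_true(is.finite(dw_loglik(5000, q = 0.999, beta = 0.5)))
  # numerically impossible observation flags as -Inf, never NaN
  expect_identical(dw_loglik(10, q = 0.1, beta = 400), -Inf)
})

test_that("shape controls the tail but not the zero mass", {
  betas <- c(0.3, 0.7, 1, 2, 4)
  p0 <- vapply(betas, function(b) ddw(0, q = 0.6, beta = b), 0)
  expect_equal(p0, rep(0.4, length(betas)))
  for (k in c(1, 3, 8)) {
    tail_mass <- vapply(betas, function(b) 1 - pdw(k, q = 0.6, beta = b), 0)
    expect_true(all(diff(tail_mass) <= 1e-12))
  }
})
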