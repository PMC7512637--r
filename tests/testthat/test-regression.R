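test_that("the log(-log) link maps the real line onto (0, 1)", {
  expect_equal(link_q(0), exp(-1))
  expect_equal(link_q(log(log(2))), 0.5)
  eta <- seq(-6, 4, by = 0.5)
  q <- link_q(eta)
  expect_true(all(q > 0 & q < 1))
  expect_true(all(diff(q) < 0))
  expect_error(link_q(Inf), "finite")
})

test_that("an intercept-only regression equals the i.i.d. fit", {
  set.seed(31)
  y <- rdw(400, q = 0.7, beta = 1.8)
  iid <- dwfit(y)
  reg <- dwreg_fit(y, matrix(1, length(y), 1))
  expect_equal(reg$loglik, iid$loglik, tolerance = 1e-6)
  expect_equal(link_q(unname(reg$coefficients[1])), iid$q, tolerance = 1e-4)
  expect_equal(reg$beta, iid$beta, tolerance = 1e-4)
})

test_that("regression MLE recovers the generating coefficients", {
  set.seed(32)
  sim <- sim_reg_data(600)
  fit <- dwreg_fit(sim$y, sim$X)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov))
  truth <- c(0.5, 0.4, -0.3, 2.1)
  est <- c(fit$coefficients, fit$beta)
  expect_true(all(abs(est - truth) < 3.5 * se))
  # fitted q honours the link exactly
  expect_equal(log(-log(fit$q)), fit$eta, tolerance = 1e-10)
  # formula interface agrees with the matrix interface
  d <- sim$d; d$y <- sim$y
  fit2 <- dwreg(y ~ x1 + x2, data = d)
  expect_equal(unname(coef(fit2)), unname(fit$coefficients), tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
})

test_that("degenerate designs and responses are rejected", {
  X <- cbind(1, c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 8, 10, 12))
  expect_error(dwreg_fit(c(0, 1, 2, 0, 1, 2), X), "rank deficient")
  X2 <- cbind(1, rnorm(6))
  expect_error(dwreg_fit(rep(0L, 6), X2), "all counts are zero")
  expect_error(dwreg_fit(c(0, 1), cbind(1, c(0, 1))), "more observations")
})

test_that("shifting a covariate moves only the intercept", {
  set.seed(33)
  sim <- sim_reg_data(500)
  f1 <- dwreg_fit(sim$y, sim$X)
  Xs <- sim$X
  Xs[, 2] <- Xs[, 2] + 3
  f2 <- dwreg_fit(sim$y, Xs)
  expect_equal(unname(f2$coefficients[2:3]), unname(f1$coefficients[2:3]),
               tolerance = 1e-4)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
  expect_equal(unname(f2$coefficients[1]),
               unname(f1$coefficients[1] - 3 * f1$coefficients[2]),
               tolerance = 1e-4)
})

test_that("predictions agree with the distribution-level functions", {
  set.seed(34)
  sim <- sim_reg_data(400)
  d <- sim$d; d$y <- sim$y
  fit <- dwreg(y ~ x1 + x2, data = d)
  nd <- data.frame(x1 = c(-1, 0, 1), x2 = c(2, 5, 8))
  q <- predict(fit, nd, type = "q")
  expect_equal(predict(fit, nd, type = "median"),
               qdw(0.5, q = q, beta = fit$beta))
  expect_equal(predict(fit, nd, type = "quantile", tau = 0.5),
               predict(fit, nd, type = "median"))
  expect_equal(predict(fit, nd, type = "mean"),
               vapply(q, function(qi) dw_mean(qi, fit$beta), 0))
  # quantiles are non-decreasing in tau and drop to 0 below 1 - q
  taus <- seq(0.05, 0.95, by = 0.05)
  qx <- predict(fit, nd[1, , drop = FALSE], type = "quantile", tau = taus[1])
  for (i in seq_along(taus)[-1]) {
    qn <- predict(fit, nd[1, , drop = FALSE], type = "quantile", tau = taus[i])
    expect_gte(qn, qx)
    qx <- qn
  }
  q1 <- predict(fit, nd[1, , drop = FALSE], type = "q")
  if (1 - q1 > 0.05)
    expect_identical(predict(fit, nd[1, , drop = FALSE], type = "quantile",
                             tau = (1 - q1) / 2), 0)
})

test_that("median effects follow the closed-form algebra", {
  fit <- structure(list(coefficients = c("(Intercept)" = 0, x1 = 0.6),
                        beta = 1.5), class = "dwreg")
  eff <- median_effects(fit)
  expect_equal(unname(eff["baseline_logM1"]), log(log(2)) / 1.5)
  expect_equal(unname(eff["x1"]), -0.4)
  fit$beta <- 3
  expect_equal(unname(median_effects(fit)), unname(eff) / 2)
  fit$coefficients[2] <- -0.6
  expect_gt(median_effects(fit)["x1"], 0)
  # zero coefficients, unit shape: baseline log(M+1) = log(log 2)
  fit0 <- structure(list(coefficients = c("(Intercept)" = 0), beta = 1),
                    class = "dwreg")
  expect_equal(unname(median_effects(fit0)), log(log(2)))
})

test_that("information criteria follow the parameter count", {
  set.seed(35)
  y <- rdw(100, 0.6, 1.5)
  fit <- dwreg_fit(y, matrix(1, 100, 1))    # k = 2 parameters
  expect_equal(fit$bic - fit$aic, 2 * (log(100) - 2))
  # hand computation on a tiny fit
  y5 <- c(0, 1, 1, 2, 4, 0, 3, 1)
  f5 <- dwreg_fit(y5, matrix(1, 8, 1))
  ll <- dw_loglik(y5, q = link_q(unname(f5$coefficients[1])), beta = f5$beta)
  expect_equal(f5$aic, -2 * ll + 4, tolerance = 1e-8)
  expect_equal(AIC(f5), f5$aic)
  expect_equal(BIC(f5), f5$bic)
})
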