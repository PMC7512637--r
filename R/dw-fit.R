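# Internal optimisation kernel shared by the i.i.d. and regression fits.
# Parameters: par = (alpha_1..alpha_p, log beta), with the linear predictor
# eta = X alpha mapped to q through the log(-log) link, q = exp(-exp(eta)).
# Writing lam = -log q = exp(eta), the log mass of y under DW(q, beta) is
#   -lam * y^beta + log(1 - exp(-lam * ((y+1)^beta - y^beta)))
# which stays finite and accurate for large counts and extreme shapes.

dw_negll <- function(par, y, X) {
  p <- ncol(X)
  beta <- exp(par[p + 1L])
  lam <- exp(drop(X %*% par[seq_len(p)]))
  a <- y^beta
  d <- (y + 1)^beta - a
  ll <- sum(-lam * a + log1mexp(lam * d))
  if (!is.finite(ll)) return(1e10)
  -ll
}

dw_negll_grad <- function(par, y, X) {
  p <- ncol(X)
  beta <- exp(par[p + 1L])
  lam <- exp(drop(X %*% par[seq_len(p)]))
  a <- y^beta
  b <- (y + 1)^beta
  d <- b - a
  # s/(1-s) with s = exp(-lam*d) equals 1/expm1(lam*d)
  r <- 1 / expm1(lam * d)
  dl_dlam <- -a + d * r
  g_alpha <- -drop(crossprod(X, lam * dl_dlam))
  ap <- ifelse(y == 0, 0, a * log(pmax(y, 1)))
  bp <- b * log(y + 1)
  dl_dbeta <- sum(-lam * ap + lam * (bp - ap) * r)
  g <- c(g_alpha, -dl_dbeta * beta)
  g[!is.finite(g)] <- 0
  g
}

# BFGS maximisation with jittered restarts on non-convergence.
dw_mle <- function(y, X, start, reltol = 1e-10, maxit = 500L, n_starts = 3L) {
  best <- NULL
  par0 <- start
  for (s in seq_len(n_starts)) {
    opt <- tryCatch(
      stats::optim(par0, dw_negll, gr = dw_negll_grad, y = y, X = X,
                   method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    if (!is.null(opt) && opt$convergence == 0L) break
    par0 <- start + stats::rnorm(length(start), sd = 0.25)
  }
  if (is.null(best))
    stop("discrete Weibull likelihood maximisation failed", call. = FALSE)
  hess <- tryCatch(
    stats::optimHess(best$par, dw_negll, gr = dw_negll_grad, y = y, X = X),
    error = function(e) NULL)
  vcov <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  if (!is.null(vcov) && any(!is.finite(vcov))) vcov <- NULL
  list(par = best$par, loglik = -best$value,
       converged = best$convergence == 0L, vcov = vcov)
}

#' Fit a discrete Weibull distribution to an i.i.d. count sample
#'
#' Maximum likelihood estimation of DW(\code{q}, \code{beta}) from a sample
#' of counts. The likelihood is maximised in the unconstrained coordinates
#' \eqn{(\log(-\log q), \log\beta)} by quasi-Newton iteration; standard
#' errors come from the inverse observed information mapped back to the
#' \eqn{(q, \beta)} scale by the delta method.
#'
#' Starting values: \code{q} at the observed fraction of non-zero counts
#' (since \eqn{f(0) = 1 - q}) and \code{beta = 1} (the geometric special
#' case).
#'
#' @param y vector of non-negative integer counts, length at least 3 with at
#'   least one non-zero value (an all-zero sample pushes \code{q} to the
#'   boundary of its domain and is rejected).
#' @param reltol relative convergence tolerance of the optimiser.
#' @return an object of class \code{"dwfit"}: a list with elements \code{q},
#'   \code{beta}, \code{se_q}, \code{se_beta}, \code{loglik}, \code{aic},
#'   \code{bic}, \code{converged} and \code{n}.
#' @examples
#' set.seed(7)
#' y <- rdw(500, q = 0.7, beta = 2)
#' fit <- dwfit(y)
#' c(fit$q, fit$beta)
#' @seealso \code{\link{dwreg}} for the regression model.
#' @export
dwfit <- function(y, reltol = 1e-10) {
  check_counts(y)
  if (length(y) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (all(y == 0))
    stop("all counts are zero: q is not identifiable inside (0, 1)",
         call. = FALSE)
  q0 <- min(max(mean(y > 0), 1e-3), 1 - 1e-3)
  start <- c(log(-log(q0)), 0)
  X <- matrix(1, length(y), 1L)
  res <- dw_mle(y, X, start, reltol = reltol)
  lq <- res$par[1L]; lb <- res$par[2L]
  q <- exp(-exp(lq)); beta <- exp(lb)
  se <- c(NA_real_, NA_real_)
  if (!is.null(res$vcov)) {
    # delta method: dq/d(lq) = -exp(lq) * q, dbeta/d(lb) = beta
    se <- c(abs(exp(lq) * q) * sqrt(res$vcov[1L, 1L]),
            beta * sqrt(res$vcov[2L, 2L]))
  }
  n <- length(y)
  structure(list(q = q, beta = beta, se_q = se[1L], se_beta = se[2L],
                 loglik = res$loglik,
                 aic = -2 * res$loglik + 4,
                 bic = -2 * res$loglik + 2 * log(n),
                 converged = res$converged, n = n,
                 par = res$par, vcov_par = res$vcov),
            class = "dwfit")
}

#' @export
print.dwfit <- function(x, ...) {
  cat("Discrete Weibull fit (maximum likelihood)\n")
  cat(sprintf("  q = %.4f (se %.4f)   beta = %.4f (se %.4f)\n",
              x$q, x$se_q, x$beta, x$se_beta))
  cat(sprintf("  logLik = %.3f   AIC = %.3f   BIC = %.3f   n = %d\n",
              x$loglik, x$aic, x$bic, x$n))
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' Variance ratio of a count sample against a model variance
#'
#' The variance ratio VR = observed variance / theoretical variance measures
#' dispersion relative to a fitted model: VR > 1 indicates overdispersion,
#' VR < 1 underdispersion. For dispersion relative to Poisson, pass the
#' sample mean as the model variance.
#'
#' @param y vector of counts (at least 2 observations).
#' @param model_variance the model's theoretical variance, > 0.
#' @return a list with \code{observed_var}, \code{theoretical_var} and
#'   \code{vr}.
#' @examples
#' y <- c(0, 1, 1, 2, 5, 8)
#' variance_ratio(y, model_variance = mean(y))  # vs Poisson
#' @export
variance_ratio <- function(y, model_variance) {
  check_counts(y)
  if (length(y) < 2L)
    stop("need at least 2 observations to compute a variance", call. = FALSE)
  if (!is.finite(model_variance) || model_variance <= 0)
    stop("'model_variance' must be > 0", call. = FALSE)
  ov <- stats::var(y)
  list(observed_var = ov, theoretical_var = model_variance,
       vr = ov / model_variance)
}

#' Dispersion regime of a discrete Weibull distribution
#'
#' Classifies DW(\code{q}, \code{beta}) as over-, equi- or underdispersed
#' relative to Poisson by comparing its variance with its mean: shapes
#' \eqn{\beta \le 1} are always overdispersed, shapes \eqn{\beta \ge 3}
#' always underdispersed, and the band in between contains both regimes
#' depending on \code{q}.
#'
#' @param q,beta distribution parameters.
#' @param tol relative tolerance within which mean and variance are declared
#'   equal ("equi").
#' @return one of \code{"over"}, \code{"equi"}, \code{"under"}.
#' @examples
#' dispersion_regime(0.3, 0.8)  # "over"
#' dispersion_regime(0.8, 3.5)  # "under"
#' @export
dispersion_regime <- function(q, beta, tol = 1e-3) {
  m <- dw_moments(q, beta)
  rel <- (m$var - m$mean) / m$mean
  if (abs(rel) < tol) "equi" else if (rel > 0) "over" else "under"
}
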