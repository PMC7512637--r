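#' Randomized quantile residuals for a discrete Weibull regression
#'
#' For a discrete response the cumulative distribution function jumps, so
#' ordinary quantile residuals are not continuous. The randomized quantile
#' residual draws \eqn{u_i} uniformly on \eqn{(F(y_i - 1), F(y_i))}
#' (with \eqn{F(-1) = 0}) under the fitted conditional distribution and
#' returns \eqn{r_i = \Phi^{-1}(u_i)}. Under a correctly specified model the
#' residuals are standard normal apart from estimation noise, so normality
#' checks (Q-Q plots, Kolmogorov-Smirnov) assess model adequacy.
#'
#' Draws are clamped to \eqn{[10^{-12}, 1 - 10^{-12}]} so the normal quantile
#' stays finite; an interval of numerically zero width falls back to its
#' midpoint with a warning.
#'
#' @param object a fitted \code{\link{dwreg}} model.
#' @param seed optional integer seed for the uniform draws (residuals are
#'   random by construction; fix the seed for reproducibility).
#' @param ... unused.
#' @return a numeric vector of residuals, one per observation.
#' @export
residuals.dwreg <- function(object, seed = NULL, ...) {
  rq_residuals(object$y, q = object$q, beta = object$beta, seed = seed)
}

#' @rdname residuals.dwreg
#' @param y vector of non-negative integer counts.
#' @param q,beta conditional DW parameters (recycled against \code{y}).
#'   Passing the true generating parameters gives residuals that are exactly
#'   standard normal; passing estimates adds estimation noise, which makes
#'   the KS test of normality conservative.
#' @export
rq_residuals <- function(y, q, beta, seed = NULL) {
  check_counts(y)
  if (!is.null(seed)) set.seed(seed)
  hi <- pdw(y, q = q, beta = beta)
  lo <- ifelse(y == 0, 0, pdw(y - 1, q = q, beta = beta))
  degen <- (hi - lo) <= 0
  u <- stats::runif(length(y), lo, hi)
  if (any(degen)) {
    warning(sprintf("%d residual interval(s) have zero width; using midpoints",
                    sum(degen)))
    u[degen] <- (lo[degen] + hi[degen]) / 2
  }
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u)
}

#' Kolmogorov-Smirnov check of residual normality
#'
#' One-sample KS test of a residual vector against the standard normal
#' distribution.
#'
#' @param residuals numeric vector of (randomized quantile) residuals.
#' @return a list with \code{statistic} and \code{p_value}.
#' @export
ks_normality <- function(residuals) {
  if (any(!is.finite(residuals)))
    stop("residuals must be finite", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(residuals, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

# rank-split indices into n_groups near-equal bins, stable in ties
# (ordered by value then original index); bins with < min_size members are
# merged with their neighbour.
group_by_percentile <- function(values, n_groups, min_size = 2L) {
  n <- length(values)
  ord <- order(values, seq_len(n))
  sizes <- diff(round(seq(0, n, length.out = n_groups + 1L)))
  gid <- integer(n)
  gid[ord] <- rep(seq_len(n_groups), times = sizes)
  tab <- tabulate(gid, n_groups)
  while (any(tab > 0 & tab < min_size) && sum(tab > 0) > 1L) {
    g <- which(tab > 0 & tab < min_size)[1L]
    nb <- if (any(tab[seq_len(g - 1L)] > 0)) max(which(tab[seq_len(g - 1L)] > 0))
          else g + min(which(tab[-seq_len(g)] > 0))
    gid[gid == g] <- nb
    message(sprintf("merged percentile group %d into group %d (too few observations)", g, nb))
    tab <- tabulate(gid, n_groups)
  }
  match(gid, sort(unique(gid)))
}

#' Covariate-grouped variance ratios
#'
#' Dispersion diagnostic for a conditional count model: observations are
#' split into \code{n_groups} groups of similar size by the percentiles of
#' the fitted linear predictor; within each group the observed variance of
#' the response is divided by the average of the model's theoretical
#' variances. Ratios near 1 across groups indicate that the model captures
#' the conditional dispersion; ratios below (above) 1 flag underdispersion
#' (overdispersion) relative to the model in that region of covariate space.
#'
#' @param fit a fitted \code{\link{dwreg}}, \code{\link{fit_poisson}} or
#'   \code{\link{fit_negbin}} model (any object with fitted linear predictors
#'   \code{eta}, response \code{y} and per-observation theoretical variances).
#' @param n_groups number of percentile groups (default 10).
#' @return a data frame with one row per group: \code{group}, \code{n},
#'   \code{observed_var}, \code{theoretical_var}, \code{vr}. Groups left with
#'   fewer than 2 observations are merged with a neighbour (with a message).
#' @examples
#' set.seed(3)
#' d <- simulate_covariates(400)
#' d$y <- simulate_dw_counts(cbind(1, d$x1, d$x2),
#'                           alpha = c(0.5, 0.4, -0.3), beta = 2.1)
#' fit <- dwreg(y ~ x1 + x2, data = d)
#' grouped_vr(fit)   # ratios scattered around 1
#' @export
grouped_vr <- function(fit, n_groups = 10L) {
  UseMethod("grouped_vr")
}

grouped_vr_core <- function(eta, y, theo_var, n_groups) {
  if (length(y) < 2L * n_groups)
    stop("need at least 2 observations per group", call. = FALSE)
  gid <- group_by_percentile(eta, n_groups)
  groups <- sort(unique(gid))
  out <- do.call(rbind, lapply(groups, function(g) {
    idx <- gid == g
    data.frame(group = g, n = sum(idx),
               observed_var = stats::var(y[idx]),
               theoretical_var = mean(theo_var[idx]))
  }))
  out$vr <- out$observed_var / out$theoretical_var
  out
}

#' @export
grouped_vr.dwreg <- function(fit, n_groups = 10L) {
  tv <- vapply(fit$q, function(qi) dw_var(qi, fit$beta), 0)
  grouped_vr_core(fit$eta, fit$y, tv, n_groups)
}

#' @export
grouped_vr.dw_baseline <- function(fit, n_groups = 10L) {
  grouped_vr_core(fit$eta, fit$y, fit$theoretical_var, n_groups)
}

#' Simulated Q-Q envelope for randomized quantile residuals
#'
#' Simulates \code{n_sim} response vectors from the fitted discrete Weibull
#' regression (parameters held fixed at the estimates by default, refit per
#' simulation on request), computes sorted randomized quantile residuals for
#' each, and returns pointwise lower/upper envelope bounds at the given
#' coverage level. With \code{n_sim = 19} and \code{level = 0.95} the bounds
#' reduce to the classical per-point minimum and maximum.
#'
#' @param fit a fitted \code{\link{dwreg}} model.
#' @param n_sim number of simulated datasets (at least 19).
#' @param level pointwise coverage level of the envelope.
#' @param refit refit the model to each simulated response vector?
#' @param seed optional integer seed.
#' @return a data frame with columns \code{theoretical} (standard normal
#'   plotting positions), \code{observed} (sorted residuals of the data),
#'   \code{lower} and \code{upper}.
#' @export
qq_envelope <- function(fit, n_sim = 100L, level = 0.95, refit = FALSE,
                        seed = NULL) {
  if (n_sim < 19L) stop("'n_sim' must be at least 19", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- fit$n
  sims <- matrix(NA_real_, n, n_sim)
  for (s in seq_len(n_sim)) {
    ys <- qdw(stats::runif(n), q = fit$q, beta = fit$beta)
    f <- fit
    if (refit) f <- dwreg_fit(ys, fit$X)
    f$y <- ys
    if (!refit) {
      hi <- pdw(ys, q = f$q, beta = f$beta)
      lo <- ifelse(ys == 0, 0, pdw(ys - 1, q = f$q, beta = f$beta))
      u <- pmin(pmax(stats::runif(n, lo, hi), 1e-12), 1 - 1e-12)
      sims[, s] <- sort(stats::qnorm(u))
    } else {
      sims[, s] <- sort(residuals(f))
    }
  }
  pr <- c((1 - level) / 2, (1 + level) / 2)
  bounds <- t(apply(sims, 1L, stats::quantile, probs = pr, type = 1L))
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
             observed = sort(residuals(fit)),
             lower = bounds[, 1L], upper = bounds[, 2L])
}

#' Observed versus expected count frequencies
#'
#' Tabulates the observed frequency of each count value against the model's
#' expected frequency \eqn{\sum_i f(c \mid x_i)}; counts above
#' \code{max_count} are pooled into a single tail bin so that both columns
#' total the sample size.
#'
#' @param fit a fitted \code{\link{dwreg}} model.
#' @param max_count largest count reported individually.
#' @return a data frame with columns \code{count} (the tail bin is labelled
#'   \code{">max_count"}), \code{observed} and \code{expected}.
#' @export
observed_expected <- function(fit, max_count = max(fit$y)) {
  y <- fit$y
  counts <- 0:max_count
  pm <- vapply(counts, function(cc)
    sum(ddw(cc, q = fit$q, beta = fit$beta)), 0)
  tail_exp <- sum(exp((max_count + 1)^fit$beta * log(fit$q)))
  obs <- vapply(counts, function(cc) sum(y == cc), 0L)
  out <- data.frame(count = as.character(counts), observed = as.numeric(obs),
                    expected = pm)
  if (tail_exp > 0 || any(y > max_count))
    out <- rbind(out, data.frame(count = paste0(">", max_count),
                                 observed = sum(y > max_count),
                                 expected = tail_exp))
  out
}
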