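---
title: "Discrete Weibull regression: model, estimation and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete Weibull regression: model, estimation and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwcount)
```

## The problem

Poisson regression forces the conditional variance of a count response to
equal its conditional mean. Real counts rarely oblige: they are
overdispersed (variance above the mean), underdispersed (below), or — the
hardest case — overdispersed for some covariate patterns and underdispersed
for others. Negative binomial (NB2) regression extends Poisson only upward:
its variance $\mu + \mu^2/k$ always exceeds the mean. The usual escape
routes for underdispersion (COM–Poisson, generalized Poisson, hyper-Poisson)
carry normalising constants with infinite sums and are expensive to fit.

`dwcount` implements a simpler alternative: a regression model built on the
type-1 discrete Weibull (DW) distribution, which covers all dispersion
regimes with two parameters.

## The distribution

$Y \sim DW(q, \beta)$ with $0 < q < 1$, $\beta > 0$ has

$$F(y) = 1 - q^{(y+1)^\beta}, \qquad
  f(y) = q^{y^\beta} - q^{(y+1)^\beta}, \qquad y = 0, 1, 2, \dots$$

Since $f(0) = 1 - q$, $q$ is the probability of a non-zero count. Special
cases anchor the intuition: $\beta = 1$ is geometric (always overdispersed),
$\beta = 2$ is discrete Rayleigh, and $\beta \to \infty$ tends to a
Bernoulli with success probability $q$ (variance $q(1-q)$, far below the
mean for moderate $q$). Numerically, the variance exceeds the mean for every
$q$ whenever $\beta \le 1$, falls below it for every $q$ whenever
$\beta \ge 3$, and the band $1 < \beta < 3$ contains both regimes depending
on $q$ — `dispersion_grid()` maps this out.

The quantile function is closed-form,
$Q(\tau) = \lceil (\log(1-\tau)/\log q)^{1/\beta} - 1 \rceil$ for
$\tau \ge 1-q$ and $0$ otherwise, which gives cheap exact sampling
(inverse transform, `rdw`) and direct median prediction.

Moments have no closed form. `dw_moments()` sums
$E(Y) = \sum_{y\ge1} q^{y^\beta}$ and
$E(Y^2) = 2\sum_{y\ge1} y\,q^{y^\beta} - E(Y)$ term by term until the terms
fall below an absolute threshold of $10^{-12}$ (and a relative-change check
holds). For heavy tails (small $\beta$ with $q$ near 1 the series needs
billions of terms) exact summation stops at $10^6$ terms and the remainder
is completed analytically: the summand varies slowly there, so the tail sum
equals the midpoint-rule integral $\int_{N+1/2}^\infty y^m e^{-\lambda
y^\beta}\,dy$ (with $\lambda = -\log q$), an upper incomplete gamma
function, to far better than the summation tolerance. Self-consistency of
this completion (moving the handover point must not move the result) is
part of the test suite.

## The regression model

Covariates enter through $q$ with the log(−log) link,

$$\log(-\log q_i) = x_i'\alpha, \qquad q_i = e^{-e^{x_i'\alpha}},$$

with a single shape $\beta$ shared across observations. The link mirrors
the log link on the scale parameter of continuous Weibull (accelerated
failure time) regression, and it makes the coefficients interpretable on
the median scale: substituting the link into the quantile formula gives

$$\log(M(x) + 1) = \frac{1}{\beta}\log\log 2 - \frac{1}{\beta}x'\alpha,$$

so $-\alpha_p/\beta$ is the change in $\log(M+1)$ per unit change of
covariate $p$ (`median_effects()`). The package treats the median
continuously on this interpretation scale; fitted integer medians come from
the ceiling in the quantile formula (`predict(fit, type = "median")`).
A covariate-dependent shape $\beta(x)$ and alternative links (logit,
probit on $q$) are deliberately out of scope; the scalar-$\beta$ model is
the one studied here.

## Estimation

`dwreg()` maximises the likelihood directly over $(\alpha, \log\beta)$ with
BFGS and analytic gradients. Writing $\lambda_i = e^{x_i'\alpha} = -\log
q_i$, the log-mass is evaluated as

$$\log f(y_i \mid x_i) = -\lambda_i\, y_i^\beta +
  \log\!\left(1 - e^{-\lambda_i\,[(y_i+1)^\beta - y_i^\beta]}\right),$$

using a two-branch `log1mexp` primitive, so no subtraction of nearly equal
probabilities ever happens in linear space. Starting values are cheap and
deterministic: the intercept from inverting the link at the marginal
estimate $\hat q_0$ = fraction of non-zero counts, slopes at zero, and
$\beta$ from the i.i.d. fit (itself started at the geometric case
$\beta = 1$). On non-convergence the optimiser restarts up to three times
from jittered starts. The relative convergence tolerance is $10^{-10}$.

Standard errors come from the inverse observed information (numerically
differentiated analytic gradient), mapped to the $(\alpha, \beta)$ scale by
the delta method; Wald intervals from these are what the recovery study
reports as CI lengths. An all-zero response is rejected outright: $\hat q$
would sit on the boundary of its open domain.

Degenerate corners are handled explicitly: exponent overflow in $y^\beta$
flags the mass as numerically zero (a $-\infty$ log-likelihood
contribution, never NaN), and simulated linear predictors extreme enough to
underflow $q$ to 0 or 1 are clamped just inside the open domain.

## Diagnostics

Because the response is discrete, residual analysis uses randomized
quantile residuals: $u_i$ uniform on $(F(y_i - 1), F(y_i))$ under the
fitted conditional distribution (with $F(-1) = 0$), $r_i = \Phi^{-1}(u_i)$.
Draws are clamped to $[10^{-12}, 1 - 10^{-12}]$ so $\Phi^{-1}$ stays
finite; zero-width intervals fall back to their midpoint with a warning.
At the *true* parameters the $u_i$ are exactly uniform, so the residuals
are exactly standard normal — the test suite confirms that a 5%-level
Kolmogorov–Smirnov test rejects in $5\% \pm 2\%$ of replicates in that
construction. With *estimated* parameters the same test becomes markedly
conservative (the Lilliefors effect: the reference distribution was fitted
to the data, and at $n = 2000$ the estimation error and the KS statistic
share the same $1/\sqrt{n}$ scale), so rejection rates far below nominal
are expected and are asserted only as an upper bound. Practically: a small
KS p-value from `ks_normality()` is strong evidence of misspecification; a
large one is weak evidence of fit.

`qq_envelope()` adds simulated pointwise envelopes to the residual Q-Q
plot. By default parameters are held fixed at the estimates across the
`n_sim = 100` simulations (refitting per simulation is available via
`refit = TRUE`); with 19 simulations and 95% coverage the bounds reduce to
the classical per-point minimum and maximum (quantile type 1).

The variance-ratio (VR) diagnostic compares observed to model-implied
dispersion: `grouped_vr()` splits observations into 10 similar-sized groups
by the percentiles of the fitted linear predictor (stable ties: ordered by
value, then by observation index; groups left with fewer than two members
merge into a neighbour), then divides each group's observed response
variance by the group average of the theoretical variances. Ratios near 1
across groups mean the model tracks the conditional dispersion;
`mixed_dispersion_experiment()` shows DW ratios hugging 1 on data whose
dispersion switches sign across the covariate space, while Poisson and NB
fits sit below 1 in most groups. `observed_expected()` complements this
with observed-vs-expected frequency tables (counts above a cut pooled into
one tail bin so both columns total $n$).

## The simulation engine and what it does (not) show

`simulate_covariates()` draws $X_1 \sim N(0,1)$ and
$X_2 \sim \mathrm{Uniform}(0,10)$; `simulate_dw_counts()` draws responses
from the conditional DW model by inverse transform. These are the study
conditions used throughout: coefficients $\alpha = (0.5, 0.4, -0.3)$ and
shape $\beta = 2.1$, sample sizes 25 and 600, 1000 replicates. With these
values $q_i$ spans roughly 0.03 to 0.98 across the covariate space, which
is precisely what makes the dispersion covariate-specific.

`recovery_study()` regenerates covariates *and* responses each replicate
(one master seed spawns an independent sub-seed per replicate, so results
are reproducible and independent of the replicate count); whether the
original covariates were fixed across replicates is ambiguous, but at
these sizes the difference only perturbs the Monte Carlo noise, not the
bias structure. Estimates from non-converged replicates are excluded and
counted, and a study with more than 5% exclusions is flagged. The reported
"MLE" column is the mean of the replicate estimates. The study reproduces
the familiar likelihood asymptotics: at $n = 600$ biases are at the third
decimal; at $n = 25$ the shape estimate carries a pronounced upward bias
(about $+0.4$ on a truth of 2.1) and every MSE inflates by an order of
magnitude or more.

What passing these simulations does *not* show: the generator draws from
the DW model itself, with clean numeric covariates, no zero inflation
beyond what DW produces, no measurement error, and no model
misspecification. Real count data can violate any of these; the
diagnostics above — not the recovery study — are the tools for that
situation.

Problem sizes used by the shipped checks (chosen to make Monte Carlo noise
small relative to the tolerances being checked): 1000 replicates for both
recovery studies, 400 replicates at $n = 2000$ for the residual-size
simulation, grids of $9 \times 20$ parameter pairs for the dispersion map
and $99 \times 90$ level/parameter combinations for the quantile oracle.

## Known limitations

* Moments for extremely heavy tails ($\beta \lesssim 0.002$ with $q$ close
  to 1) can overflow even the analytic tail completion; the functions warn
  and return partial sums.
* The NB baseline's dispersion estimate diverges on equi/underdispersed
  data; it is capped at $10^8$ (the Poisson limit) with a warning.
* Standard errors assume the usual regularity of the MLE; at $n = 25$ the
  Wald intervals are visibly optimistic, as the recovery study's small-n
  block shows.
* Zero-inflated extensions of the DW model are not implemented.
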