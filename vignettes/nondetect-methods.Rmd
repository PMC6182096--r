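---
title: "Non-detects as counts: models, estimators, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-detects as counts: models, estimators, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndcount)
```

## The sampling model

Everything in `ndcount` rests on one observation model. A source contains
organisms at true concentration $c$ (organisms per liter). An analysed
sample of volume $V$ liters captures a Poisson number of organisms with
mean $cV$, and the method observes each captured organism with analytical
recovery $R \in (0, 1]$, so the recorded count is

$$x \mid c, R \sim \text{Poisson}(c V R).$$

A non-detect is the event $x = 0$, with probability $e^{-cVR} > 0$ at every
concentration. Nothing is censored: the zero is as much a measurement as a
five. The package's estimators, posteriors, and sensitivity metrics are all
consequences of this likelihood.

Three recovery profiles are supported. *Perfect* ($R = 1$) and *constant*
($R = p$) recovery leave the Poisson form intact. Under *beta-distributed*
recovery, $R \sim \text{Beta}(a, b)$ varies between samples and the
non-detect probability becomes the mixture

$$P(x = 0 \mid c) = \mathbb{E}_R\!\left[e^{-cVR}\right]
  = {}_1F_1(a;\, a + b;\, -cV),$$

a confluent hypergeometric function. By convexity of the exponential
(Jensen's inequality), a variable recovery always yields a *higher*
non-detect probability than a constant recovery with the same mean — spread
in recovery hurts sensitivity even when the average is unchanged. The test
suite checks this ordering at random parameter values.

## Method sensitivity limit

`msl(volume, recovery, alpha)` returns the concentration $c^\*$ at which
$P(\text{ND}) = \alpha$. The default $\alpha = 0.01$ treats a non-detect as
"improbable" below 1% probability; $\alpha$ is a reporting convention, not
an estimate, and is exposed as a parameter. For perfect and constant
recovery the closed forms $\ln(1/\alpha)/V$ and $\ln(1/\alpha)/(pV)$ are
used directly. For beta recovery the root is bracketed at
$[0,\ \ln(1/\alpha)/(V\,\mathbb{E}[R])]$ — the constant-recovery MSL at the
mean recovery, which Jensen's inequality guarantees is a lower bound for
the target — doubled until the probability falls below $\alpha$, and solved
with `uniroot` at tolerance $10^{-12}$.

```{r}
c(perfect = msl(1), constant = msl(1, recovery_constant(0.4)),
  beta = msl(1, recovery_beta(2, 3)))
```

A 1-L method with 40% mean recovery that varies as Beta(2, 3) cannot
reliably see concentrations below ~32 organisms/L — over seven times the
perfect-recovery figure, and far above the nominal "1 organism per volume"
detection limit.

## Evaluating the hypergeometric function

No installed package exposes $_1F_1$, so `ndcount` evaluates it from its
series. For the argument $-cV \le 0$ the direct series alternates and
cancels catastrophically, so the Kummer transformation
$_1F_1(a; b; -t) = e^{-t}\,{}_1F_1(b - a;\, b;\, t)$ is applied first; the
transformed series has all-positive terms. Because those terms grow to
order $e^{t}$ before the $e^{-t}$ prefactor is applied, the series is
accumulated in log space with incremental log-sum-exp, which is stable for
any $t$ representable in double precision; beyond $t = 5\times 10^4$ the
code switches to adaptive quadrature of the beta mixture. Tests require
agreement between the series and quadrature routes to $10^{-8}$ relative
over the working range $cV \in [0, 200]$.

## The posterior from a single count

With a semi-infinite uniform prior on $c$ and perfect or constant recovery
$p$, the posterior after observing count $x$ in volume $V$ is

$$c \mid x \sim \text{Gamma}(x + 1,\ pV).$$

The flat prior is improper but the posterior is proper for every $x \ge 0$,
so it is implemented directly as a gamma distribution with no truncation
constant. Beta-distributed recovery is *not* conjugate here and is
deliberately out of scope for the posterior module. The practical use is
tail probabilities against a purported MDL:

```{r}
prob_exceeds(posterior_from_count(0, 1), 1)       # ND, yet P(c > 1/L) ~ 37%
1 - prob_exceeds(posterior_from_count(2, 1), 1)   # x = 2, yet P(c < 1/L) ~ 8%
```

## The five estimators

Given a set of samples with non-detects, the legacy approaches operate on
*reported concentrations* (detects as $x/V$, non-detects as "< $1/V$" with
the per-sample limit $1/V$ — limits differ between samples of different
volume):

- **A** drops the non-detects and fits a lognormal by MLE to the detects;
- **B**, **C** substitute the limit (or half of it) and fit the lognormal
  MLE to all values;
- **D** maximises the left-censored lognormal likelihood: density terms
  for detects, $F_{LN}(\text{limit})$ for non-detects.

**E** returns to the raw counts and fits the Poisson-lognormal hierarchy
$c_i \sim \text{Lognormal}(\mu_L, \sigma_L)$,
$x_i \sim \text{Poisson}(c_i V_i)$, maximising
$\sum_i \log \int \text{Pois}(x_i; cV_i)\, f_{LN}(c)\, dc$. TNTC records
enter as survival terms $P(X \ge \text{threshold})$ inside the integral.

All fits report the *arithmetic* mean and SD of the fitted lognormal,
$\hat\mu = e^{\mu_L + \sigma_L^2/2}$ and
$\hat\sigma = \hat\mu\sqrt{e^{\sigma_L^2} - 1}$, the scale on which source
water statistics are compared. The uncensored `sdlog` MLE uses the
$n$-divisor (the maximum likelihood estimator), not $n - 1$.

```{r}
fits <- fit_all_approaches(load_fixture("calgary_giardia_2012"))
sapply(fits, function(f) round(c(mean = f$arith_mean, sd = f$arith_sd), 4))
round(bias_ratio(fits)$ratios, 2)
```

On this dataset every legacy approach overstates the mean 1.9–3.9-fold
relative to the count model. A caution on orderings: substituting the full
limit (B) rather than half of it (C) provably raises `meanlog` but not
necessarily the arithmetic mean, because halving the limits can also shrink
`sdlog`; the arithmetic ordering holds on this dataset but is not a theorem,
and the tests assert only the `meanlog` version in general.

## Numerical choices

*Quadrature.* The Poisson-lognormal integral is evaluated by Gauss–Hermite
quadrature in log-concentration with 61 nodes (nodes from
`pracma::gaussHermite`, cached). With counts below ~10 and the 50–64 L
volumes of the worked dataset the integrand is smooth on the Gaussian
scale; tests require agreement with adaptive quadrature (`integrate`, the
cross-check route) to $10^{-6}$. At $\sigma_L = 0$ the mixture degenerates
and the code returns the plain Poisson log-likelihood at $c = e^{\mu_L}$.

*Optimisation.* Approaches D and E optimise over $(\mu_L, \log \sigma_L)$
(the log transform keeps $\sigma_L$ positive without constraints) by
Nelder–Mead with relative tolerance $10^{-12}$ from three starts: a
moment/pooled-count start, a substitution-based start, and a perturbed
start. Multi-start guards against the flat, banana-shaped likelihood
surfaces that tiny datasets produce. Non-convergence is reported on the
fit (`converged = FALSE`) rather than raised.

*Degenerate inputs.* All-negative MPN series return the boundary MLE 0;
all-positive series are flagged non-identifiable (`estimate = Inf`) rather
than capped, since the likelihood increases without bound. All-zero count
datasets are rejected by the Poisson-lognormal fit: without an informative
prior no finite MLE exists.

*Units.* Concentrations are per liter and volumes in liters everywhere
inside the package; "per 100 L" appears only in `read_reported(units =
"per_100L")` conversion and the display helper `format_reported_per_100L()`.
Analysis paths never round; 2-significant-figure display values are
formatting only.

## The synthetic-data generator

`simulate_counts()` draws exactly the structure the estimators assume:
lognormal concentrations across sampling events, a recovery fraction per
sample from the chosen profile, then Poisson counts — in that documented
stream order under one seed, so runs are bit-reproducible. Its default-free
signature forces the caller to state the scenario; the bias study in
`analysis/04_bias_simulation.R` uses $n = 24$ events (two years of monthly
monitoring), $\sigma_L = 0.83$ and 50-L volumes, with $\mu_L$ swept from
$-5.3$ (the worked dataset's fitted value, ~75% non-detects) to $-3.3$
(few non-detects). Because the generator *is* the assumed model, passing
tests establish internal consistency — correct likelihoods, estimators and
probabilities under lognormal-Poisson sampling — not robustness to real
data features the model omits: temporal autocorrelation, non-Poisson
clustering of organisms, matrix-dependent recovery drift, or mis-specified
concentration distributions.

*Parameter-recovery precision.* At the simulation-study conditions
($n = 500$, $\mu_L = -5.3$, $\sigma_L = 0.83$, 50-L samples) the expected
count per sample is only ~0.36, and the numerically computed Fisher
information gives an asymptotic standard error of 0.13 for $\hat\mu_L$.
The median absolute error across simulation batches is therefore expected
around 0.09, and individual 20-dataset batches straddle 0.1 — a batch
median slightly above 0.1 reflects sampling noise at these conditions, not
estimator bias (the mean error is statistically zero and the optimiser is
verified converged).

## Known limitations

- Approach E does not adjust for analytical recovery; extending the
  marginal likelihood with a recovery distribution is possible but the
  integral becomes two-dimensional and was not pursued.
- The posterior module covers one count at a time under perfect/constant
  recovery; multi-sample inference belongs to the Poisson-lognormal fit.
- Only the lognormal is offered for between-event concentration
  variability; model selection among candidate distributions is out of
  scope.
- MPN support covers arbitrary volume series but not standards-table
  dilution designs.
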