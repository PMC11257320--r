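---
title: "Testing odds-ratio homogeneity with combined bilateral and unilateral data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing odds-ratio homogeneity with combined bilateral and unilateral data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatOR)
```

## The data and the model

`bilatOR` analyzes stratified two-arm studies on paired organs in which a
subject contributes either both organs (bilateral; the number of
responding organs is 0, 1 or 2) or a single organ (unilateral; 0 or 1).
Within stratum $j \in \{1,\dots,J\}$ and group $i$ (1 = treatment,
2 = control), every organ responds with probability $\pi_{ij}$ and the
two organs of one subject share an intraclass correlation $\rho_j$ — the
correlation is assumed equal for the two groups of a stratum (treatment
should not change how strongly a patient's organs co-respond) but may
differ across strata.  A bilateral subject's count of responding organs
is then trinomial with

$$p_0 = (1-\pi)(\rho\pi - \pi + 1), \qquad
  p_1 = 2\pi(1-\pi)(1-\rho), \qquad
  p_2 = \pi(\rho + \pi - \rho\pi),$$

which interpolates between Binomial$(2,\pi)$ at $\rho = 0$ and a single
Bernoulli at $\rho = 1$; unilateral subjects are Bernoulli$(\pi_{ij})$.
The treatment effect in stratum $j$ is the odds ratio
$\theta_j = \pi_{1j}(1-\pi_{2j})/(\pi_{2j}(1-\pi_{1j}))$, and the null
hypothesis of interest is $H_0:\theta_1=\dots=\theta_J$.

Counts enter as a `stratified_counts` object (constructor,
reader/writer for a delimited long format, and two built-in clinical
datasets via `or_fixture()`).  Cells absent from an input file are zero,
so purely bilateral and purely unilateral designs are ordinary special
cases, not sentinels.  Validation requires non-negative integer cells and
at least one subject per group per stratum.

## Maximum likelihood

All log-likelihoods drop the multinomial constants, so differences of
log-likelihoods — the only quantities the tests use — are exact.

**Unconstrained fit.**  Strata are independent.  For fixed $\rho_j$, the
stationarity condition of the stratum log-likelihood in $\pi_{ij}$ clears
to a cubic polynomial whose admissible root is available in closed form;
the package derives the cubic's coefficients symbolically from the
likelihood and solves it with the trigonometric (three-real-roots)
formula, falling back to `polyroot()` in degenerate configurations (for
a purely unilateral group the cubic collapses onto the binomial MLE
$n_1/n_+$).  The fit alternates this exact coordinate update for
$\pi_{1j}, \pi_{2j}$ with a scalar Fisher-scoring step for $\rho_j$
using the expected information

$$I(\rho_j) = \sum_i m_{+ij}\,\pi_{ij}(1-\pi_{ij})\left[
  \frac{\pi_{ij}}{\rho_j\pi_{ij}-\pi_{ij}+1} + \frac{2}{1-\rho_j} +
  \frac{1-\pi_{ij}}{\rho_j+\pi_{ij}-\rho_j\pi_{ij}}\right],$$

with step-halving whenever a step would leave the parameter box or
decrease the likelihood.  The intraclass correlation starts at the
deterministic value 0.5 rather than a random draw: the profile in
$\rho$ is well behaved, and a fixed start makes every fit reproducible.

**Constrained fit.**  Under $H_0$ the constraint is absorbed by the
reparameterization $\pi_{2j} = \pi_{1j}/(\pi_{1j}(1-\theta)+\theta)$.
The constrained stratum log-likelihood is implemented *by substitution*
of this image into the unconstrained log-likelihood — not as a separate
transcribed formula — so the identity
$l_{j\mid\theta}(\pi_{1j},\rho_j,\theta) =
l_j(\pi_{1j},\pi_{2j}(\pi_{1j},\theta),\rho_j)$ holds exactly by
construction, and all constrained derivatives follow by the chain rule
from the analytic unconstrained scores.  The fit iterates (a) a
safeguarded Newton update of the common odds ratio on the **log** scale
(positivity for free, near-quadratic curvature, matching the
log-transformation argument used for the Wald test) holding the
per-stratum $(\pi_{1j},\rho_j)$ fixed, then (b) a 2×2 Fisher-scoring
update of $(\pi_{1j},\rho_j)$ per stratum with the expected information
mapped through the constraint Jacobian
$\partial\pi_{2j}/\partial\pi_{1j} = \theta/(\pi_{1j}(1-\theta)+\theta)^2$.
Initial values average the unconstrained estimates; the odds ratio is
initialized at the geometric mean of the per-stratum estimates clamped to
$[10^{-2},10^2]$, because a boundary stratum can make the arithmetic mean
arbitrarily large while the log-scale average stays informative.

**Numerical policy.**  Probabilities are evaluated on
$[10^{-10},1-10^{-10}]$ and $\rho$ on $[0, 1-10^{-10}]$; a clamp that
binds at the solution raises a per-parameter boundary flag.  Convergence
requires the maximum parameter change below $10^{-8}$ *and* the
log-likelihood change below $10^{-10}$, with at most 500 outer
iterations.  If the structured iteration stalls or ends non-stationary,
the fit falls back to direct bounded multi-start maximization
(`optim` L-BFGS-B) and keeps whichever solution has the higher
likelihood.  Both fitters are property-tested against independent
multi-start direct maximization on randomized datasets (agreement to
$10^{-5}$ in log-likelihood).

## The three statistics

* **Likelihood ratio**: $T_{LR} = 2(\hat\ell - \tilde\ell)$, clamped at
  zero.
* **Score**: at the constrained maximum the nuisance scores in
  $(\pi_{1j},\rho_j)$ vanish (asserted in the tests, not assumed), so the
  stratum contribution reduces to
  $U_j^2\,[I_j^{-1}]_{\theta\theta}$ where $U_j$ is the analytic
  derivative of the constrained stratum log-likelihood in $\theta$ and
  $I_j$ the 3×3 expected information in $(\theta_j,\pi_{1j},\rho_j)$.
* **Wald**: consecutive-strata contrasts of
  $\log\hat\theta_j = \mathrm{logit}\,\hat\pi_{1j} -
  \mathrm{logit}\,\hat\pi_{2j}$, with delta-method covariance
  $g_j I_j^{-1} g_j^{\top}$,
  $g_j = \mathrm{diag}(1/(\pi_{1j}(1-\pi_{1j})),\,
  1/(\pi_{2j}(1-\pi_{2j})),\, 1/\rho_j)$.  Any full-rank contrast basis
  gives the same value (a tested invariance).

All expected-information blocks are assembled analytically from the
category probabilities as
$\sum_t (\partial p_t/\partial x)(\partial p_t/\partial y)/p_t$ per
group (plus the binomial term for unilateral subjects) and are
cross-validated in the test suite against numerically averaged negative
Hessians.  Expected (rather than observed) information is used
throughout, consistent with the Fisher-scoring updates of the fitters.
P-values are upper-tail $\chi^2_{J-1}$; no small-sample corrections are
applied.

## Boundary solutions

A group with no responders (or all responders) drives its $\hat\pi$ to
the clamp bound.  The reported log-likelihood is then the boundary
supremum, which is the right ingredient for $T_{LR}$; the score test
evaluates at the constrained fit, which is typically interior; but the
Wald statistic involves $\mathrm{logit}\,\hat\pi$ and its variance, both
of which degenerate.  The package therefore reports the Wald statistic
with a prominent instability warning instead of refusing it.  In the
built-in myopia dataset the Female control group has zero responders:
point estimates for that cell depend entirely on where an iterative
algorithm is stopped, which is why the package reports the boundary flag
rather than any particular interior-looking stopping value, and why the
Wald statistic for that dataset should not be trusted (the likelihood
ratio and score tests remain usable).

## Monte-Carlo machinery

`sim_spec()` fixes a scenario: strata count $J$, per-group bilateral and
unilateral sample sizes ($m_{+ij} = n_{+ij}$ in all tabulated designs,
unequal sizes permitted), $\pi_{1j}$, $\rho_j$, and an odds-ratio vector
($\theta$ constant under the null; patterns such as $(1,2)$ or
$(1,2,3,4)$ under alternatives).  `sample_counts()` draws binomial
unilateral and trinomial bilateral counts; `empirical_size()` and
`empirical_power()` fit both models per replicate and report percent
rejections of each statistic at the $\chi^2_{J-1}$ critical value,
together with Monte-Carlo standard errors
$100\sqrt{p(1-p)/\text{reps}}$.  Replicates whose fits fail even after
the direct-maximization fallback are excluded from the denominator and
counted, with a warning if they exceed 0.1% — exclusion-with-reporting
keeps the estimate auditable.  `random_settings_study()` draws
$\pi_{1j},\rho_j$ uniformly on $(0.02, 0.98)$ and $(0,1)$ and a common
$\theta$ on $[1,4]$ (the implied $\pi_{2j}$ is automatically inside
$(0,1)$ for any positive $\theta$, which the code asserts), running a
null-hypothesis study per setting from per-setting seeds derived from
the master seed so that results do not depend on evaluation order.

The generator emulates the designed sampling scheme exactly — fixed
group sizes, exact trinomial category probabilities, independence across
subjects and strata.  It does not emulate features of real studies such
as missingness that is informative about severity, misclassification of
the response, or correlation that differs between arms; passing
simulation checks therefore says nothing about robustness to those
violations.

Default replicate counts are 50,000 for fixed-grid cells and 10,000 per
random setting; every function takes a `reps` override for desk-scale
runs, and the test suite uses 2,000–3,000 replicates per asserted cell
with tolerances of three Monte-Carlo standard errors at the replicate
count actually used.  The acceptance script uses 10,000 replicates per
cell.

## Known limitations

* No standard errors or confidence intervals for the fitted parameters
  are produced; the package tests homogeneity only.
* The asymptotics are $\chi^2_{J-1}$ large-sample results; with very
  small or sparse strata the likelihood-ratio and score tests run
  conservative and exact methods would be preferable.
* Subject-level (per-organ) data must be aggregated to counts before
  entry; covariates other than the stratum are not modeled.
* With no bilateral subjects in a stratum, $\rho_j$ is not identifiable
  and is fixed at 0 with the corresponding information rows dropped.
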