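---
title: "Bootstrap confidence intervals for GSCA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap confidence intervals for GSCA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscaboot)
```

## The model and its estimator

Generalized structured component analysis (GSCA) is a component-based
approach to structural equation modeling.  Each construct is an exact
weighted composite of its block of indicators,
$\gamma_p = Z w_p$, constrained to unit variance; there are no latent
factors and no distributional assumptions.  Three parameter matrices are
estimated jointly: weights $W$ (indicator $\to$ component), loadings $C$
(component $\to$ its own indicators), and path coefficients $B$ (component
$\to$ component).  All of them minimize one least-squares criterion
$$
f(W, C, B) \;=\; \mathrm{SS}\!\left(Z - Z W C\right)
  \;+\; \sum_{p \,\in\, \text{endogenous}}
        \mathrm{SS}\!\left(Z w_p - Z W b_p\right),
$$
the summed squared residuals of every indicator regressed on its component
plus every endogenous component regressed on its predecessors.

`gsca_fit()` minimizes $f$ by alternating least squares:

* **Loadings and paths given weights** are per-column ordinary least
  squares solutions.  With unit-variance components the free loadings are
  simply $c_{pj} = \gamma_p' z_j / n$, and each endogenous column of $B$
  solves a small normal system among component scores.
* **Weights given loadings and paths** are updated component by component
  in index order.  Restricted to $w_p$, the criterion is
  $\text{const} - 2 a' w_p + \kappa \, w_p' M w_p$ with
  $M = Z_p' Z_p$; under the normalization $w_p' M w_p = n$ the quadratic
  term is constant, so the constrained block minimizer is
  $w_p \propto M^{-1} a$, rescaled to the constraint.  Because each step is
  an exact block minimizer, the criterion is non-increasing across
  iterations — a property the test suite asserts at every iteration.

Everything runs on the $J \times J$ cross-product matrix $Z'Z$, so the cost
per iteration does not grow with $n$; this is what makes the Monte Carlo
study below affordable in plain R.

Numerical choices:

* **Standardization** uses the divisor-$n$ convention (column sum of
  squares $= n$), which makes the unit-variance normalization
  $\mathrm{diag}(W'Z'Z\,W) = n I$ exact.  Bootstrap and jackknife resamples
  are re-standardized before refitting: the estimator's preprocessing is
  part of the resampled statistic.
* **Initialization** sets every free weight to 1 before normalization.
  The criterion for this model class is well behaved, and the closed-form
  checks (a single block converges to the first principal component)
  anchor the solution; bootstrap and jackknife refits are warm-started
  from the original sample's converged weights, which changes nothing in
  the solutions (verified against cold starts) and roughly halves
  simulation cost.
* **Convergence** stops when the absolute decrease of $f$ falls below
  `tol = 1e-5`, with `max_iter = 300`.
* **Sign indeterminacy.**  Each component's sign is fixed on the original
  fit so the sum of its loadings is non-negative; every resample refit is
  then aligned to the original with `sign_align()` (flip a component when
  the inner product of its weight vectors is negative; an exact zero keeps
  the candidate).  Without this, bootstrap distributions would be
  sign-flip bimodal and intervals meaningless.
* **Degenerate blocks.**  The weight-update normal equations are always
  consistent, so a rank-deficient block (e.g. duplicated indicators) is
  solved by the minimum-norm solution; a direction of zero variance keeps
  the previous weights.  Singular structural systems and non-converged
  resamples are classed inadmissible; the bootstrap redraws them (counted,
  never silently dropped) and aborts if more than 10% of resamples fail.

## The three interval methods

All three methods consume one shared bootstrap pass: $B$ resamples of $n$
rows with replacement, refit, sign-aligned, collected into a $B \times K$
matrix of replicate parameter vectors.

**Percentile.**  The interval between the $\alpha/2$ and $1-\alpha/2$
order statistics of the replicates, with ranks
$j = \mathrm{round}(B\alpha/2)$, $k = \mathrm{round}(B(1-\alpha/2))$,
clamped to $[1, B]$.  The bracket is read as round-to-nearest because it
reproduces the canonical 25th/975th ranks at $B = 1000$, $\alpha = 0.05$
exactly and degrades gracefully for non-integer products.  Note that
half-integer products (e.g. $B = 100$, $\alpha = 0.05$) sit exactly on a
rounding boundary; for interval comparisons across methods, choose $B$ so
that $B\alpha/2$ is an integer.

**BCa.**  Percentile-type, with the quantile levels adjusted by a
bias-correction factor $\hat z_0 = \Phi^{-1}(c/B)$, where $c$ counts
replicates strictly below the original estimate, and an acceleration
factor $\hat a$ computed from one jackknife (leave-one-out) pass:
$$
\hat a = \frac{\sum_i (\bar\theta_{(\cdot)} - \hat\theta_{(-i)})^3}
              {6\left[\sum_i (\bar\theta_{(\cdot)} -
               \hat\theta_{(-i)})^2\right]^{3/2}}.
$$
Ties with the original estimate are not counted in $c$, and $c$ is clamped
to $[0.5, B - 0.5]$ so the degenerate counts 0 and $B$ give finite
$\hat z_0$ (the standard continuity correction).  When all leave-one-out
estimates are equal, $\hat a = 0$ by convention.  With $\hat z_0 = 0$ and
$\hat a = 0$ the interval is exactly the percentile interval, a reduction
the tests assert.  The jackknife is run once per original sample and its
acceleration reused for all of that sample's BCa intervals.

**Student's t.**  $\hat\theta \pm t_{n-1}(1 - \alpha/2)\,\widehat{se}$,
with $\widehat{se}$ the bootstrap standard deviation (divisor $B-1$) and
degrees of freedom $n - 1$ from the original sample size.  The companion
critical ratio is $\hat\theta / \widehat{se}$.

## The built-in population model

The simulation population has six components, three indicators each, with
standardized loadings 0.7, 0.8, 0.9 in every block.  Four components are
exogenous and equicorrelated; two are endogenous:
$\gamma_5 \sim \gamma_1 + \gamma_2$ and
$\gamma_6 \sim \gamma_1 + \gamma_2 + \gamma_3 + \gamma_5$, with the six
path coefficients $(-0.25, -0.2, -0.75, 0.55, 0.35, -0.15)$.  Residual
variances scale every component to unit variance, so the explained
variances are purely structural quantities — `population_r2()` returns
0.168 for $\gamma_5$ and 0.383 for $\gamma_6$, independent of the
loadings.  The exogenous correlation (0.6551796) is the unique value for
which this wiring reproduces those two explained variances; an exhaustive
search over assignments of the six coefficients under a uniform exogenous
correlation admits exactly one solution, which is the one implemented.
$\gamma_4$ carries no structural path and enters only through its
correlations.

```{r population}
pop <- gsca_population()
round(pop$r2, 3)
```

**Composite versus factor construction of sigma.**  Two constructions of
the implied indicator correlation matrix are provided.  The default
(`sigma_mode = "composite"`) builds a *composite* population: within each
block the indicators are equicorrelated at the uniquely determined value
for which a unit-variance weighted composite reproduces the loadings
exactly as indicator–composite covariances.  For loadings
$(0.7, 0.8, 0.9)$ this gives within-block correlation exactly $1/2$ and
generating weights $(0.2, 0.4, 0.6)$.  Under this construction a composite
estimator like GSCA recovers the population paths with little structural
bias (the $-0.75$ path's population-level estimand is $-0.69$), which is
the appropriate reference point for scoring coverage of a composite
method.  The alternative `sigma_mode = "factor"` uses the common-factor
construction ($\lambda_i \lambda_j$ within blocks, unique variances on the
diagonal); under it GSCA's path estimands are strongly attenuated (the
$-0.75$ path drops to $-0.48$), so coverage of the factor parameters
confounds interval behavior with structural bias — that mode is kept for
studying exactly that confounding, not as the default.

**Data generation.**  `generate_normal()` mixes i.i.d. standard normals
with the lower Cholesky factor of sigma.  `generate_lognormal()`
exponentiates independent normals into lognormal variates, standardizes
each column, and post-multiplies by the transpose of the lower Cholesky
factor, so the population covariance is again sigma while the margins are
strongly right-skewed and leptokurtic.  Moments use the plain fourth
standardized moment (normal $= 3$); no excess kurtosis anywhere.
Because sample skewness and kurtosis of heavy-tailed data are severely
downward biased at realistic $n$, the generator's non-normality is
reported as moments averaged over replications *and* indicators within a
condition (`replication_moments()`); per-indicator extremes — the first
Cholesky coordinate is a pure standardized lognormal — are far more
dispersed and are reported alongside, not summarized.

What the generator emulates: correlated blocks, known composite structure,
controlled non-normality.  What it does not: missing data, discrete or
bounded indicators, heteroskedasticity, model misspecification.  Passing
tests therefore speak to interval behavior under a correctly specified
composite population, not to robustness against those features of real
data.

## The Monte Carlo harness

`simulation_design()` crosses distributions (normal, lognormal) with
sample sizes (default 50, 100, 200, 500), 500 replications per cell and
$B = 1000$ resamples, at $\alpha = 0.05$.  Each replication generates one
sample, fits the model, runs one bootstrap pass shared by the percentile
and BCa intervals, and one jackknife pass for the acceleration.  All
randomness derives from a single master seed (cell seeds are spaced
offsets; each bootstrap pass draws from one RNG stream seeded once), so
the full study is a pure function of its design.  An earlier per-replicate
seeding scheme (`seed + b`) was found to share most resampling streams
between adjacent replications, correlating their bootstrap noise and
inflating the variance of observed coverage beyond binomial; the
single-stream design removes this.

`coverage_balance()` scores each interval against the population value
with inclusive endpoints (`lower <= theta <= upper`; the distinction is
measure-zero and fixed for determinism) and returns the exact ternary
partition coverage / miss-below / miss-above.  Loadings are aggregated per
population loading value (unweighted mean over the six components), paths
per population path value.

The test suite exercises a scaled-down study — two cells
(normal/lognormal at $n = 100$), 100 replications, $B = 200$ — which keeps
the full pipeline under a few minutes on one core while leaving the
binomial band around nominal coverage wide but meaningful.  The interval
calibration property is checked on the sample mean of i.i.d. normal data
($n = 50$, 1000 trials, $B = 399$), where all three methods should cover
at close to the nominal 95%.

## Known limitations

* At $n = 100$ the resampling estimators (bootstrap and jackknife agree
  with each other) underestimate the sampling variance of the path between
  the two endogenous composites by a few percent, so its percentile
  coverage runs near 0.90 rather than 0.95; the effect disappears by
  $n = 500$.  This is a small-sample property of that heavily
  collinear subproblem, not an implementation artifact.
* The ALS estimator returns a local minimizer; for the model classes here
  the monotone criterion plus the principal-component closed form leave no
  observed multimodality, but pathological blocks (near-zero eigenvalues)
  are flagged inadmissible rather than explored with restarts.
* Only complete data are supported, and only the three interval methods
  implemented; there is no studentized (per-resample SE) bootstrap and no
  basic/reverse-percentile interval.
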