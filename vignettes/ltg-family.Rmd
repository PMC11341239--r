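---
title: "The Lomax-tangent family: model, estimation and numerical methods"
author: "ltgfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Lomax-tangent family: model, estimation and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltgfam)
```

## The model

The Lomax-tangent generalized (LT-G) family is a transformed–transformer
construction: a Lomax generator density $r(t) = (k/s)(1 + t/s)^{-k-1}$
on $(0, \infty)$ is integrated up to the link value
$W[G(x)] = \tan(\pi G(x)/2)$, where $G$ is any absolutely continuous
baseline cdf.  The link maps the unit interval onto the generator's
support, so the composition

$$F(x) = 1 - \left[1 + \frac{\tan(\pi G(x)/2)}{s}\right]^{-k}$$

is again a proper cdf, with density

$$f(x) = \frac{\pi k}{2s}\, g(x)\, \sec^2\!\frac{\pi G(x)}{2}
  \left[1 + \frac{\tan(\pi G(x)/2)}{s}\right]^{-k-1}.$$

(The generator constant is pinned to $c = 1/s$; any other choice fails
to normalize the closed form above.)  The generator shape $k$ controls
how heavily the upper tail of the baseline is re-weighted — small $k$
thickens the right tail dramatically — while $s$ rescales the link.
The two extra parameters buy hazard-shape flexibility: with a Weibull
baseline the hazard can be increasing, decreasing, unimodal or
bathtub-shaped, and the Rayleigh sub-model admits genuinely bimodal
densities (`ltg_critical_points()` exhibits a case with two interior
maxima at $k \approx 0.097$, $s \approx 0.29$, $\beta = 1$).

Assumptions worth stating: observations are complete (no censoring),
independent, and strictly inside the baseline support.  Values at or
below the support's lower end are rejected by `ltg_fit` with their
indices; `dltg` itself returns density 0 (log-density $-\infty$)
outside the support rather than erroring, so likelihood exploration
degrades gracefully.

### Parameterizations

The four shipped baselines use the conventions under which the family's
published benchmark tables are reproducible: Weibull
$G = 1 - e^{-(x/a)^b}$ ($b$ shape, $a$ scale, same units as the data);
Rayleigh $G = 1 - e^{-\beta x^2}$ ($\beta$ in inverse squared data
units); exponential $G = 1 - e^{-\beta x}$ ($\beta$ a rate); and the
*one-parameter* gamma $g = x^{\beta-1}e^{-x}/\Gamma(\beta)$, written
rate-free.  The gamma accepts an optional second parameter (a scale
$\theta$, default 1) as an extension beyond the canonical form.
Everywhere the full parameter vector is ordered $(k, s, \xi)$.

## Numerical evaluation

**The upper tail.**  $\tan(\pi G/2)$ overflows as $G \to 1$, and for
right-skewed data the baseline cdf is within machine epsilon of 1 well
inside the sample range.  Evaluated naively, the log-likelihood surface
acquires noise of order $10^{-1}$ — enough to create spurious optima
*below* the true one.  All family functions therefore switch, at
$G = 1/2$, to the survival form
$\tan(\pi G/2) = 1/\tan(\pi S/2)$ and
$\log\cos(\pi G/2) = \log\sin(\pi S/2)$ with $S = 1 - G$ computed
directly from the baseline's upper tail, and assemble
$\log(1 + \tan/s)$ via `log1p`.  The survival function is carried in
log space end to end.  The quantile function likewise feeds
$\frac{2}{\pi}\arctan(1/z)$ to the baseline's upper-tail quantile when
the link value $z$ exceeds 1.

**Quadrature.**  Raw moments and the mgf are integrated on the quantile
scale, $\mu'_r = \int_0^1 Q(u)^r\,du$, over a geometric ladder of
panels accumulating toward $u = 1$ (at $10^{-1}, 10^{-2}, \dots,
10^{-13}$ from the endpoint), each by adaptive quadrature at relative
tolerance $10^{-10}$; nodes within double epsilon of 1 are clamped to
$1 - 10^{-15}$.  For the shipped baselines $Q(u)$ grows only like a
power of $\log(1/(1-u))$, so all moments exist; a non-finite panel
raises an explicit "moment does not exist" error rather than returning
`NaN`.  The mgf diverges for arguments at or beyond the effective decay
rate of the upper tail and says so.

**Shape analysis.**  Critical points of the density and hazard use the
analytic derivative of the log function (assembled from the baseline's
$g'/g$), a 2000-point sign-change scan over the central 99.98%
quantile range (configurable), `uniroot` refinement, and
classification by the numerically differentiated curvature.  Closed
forms of the second derivative are deliberately not production code.

## Series expansions

The cdf admits the formal exp-G expansion
$F = \sum_{i \ge 1}\sum_{j \ge 0} W_{i,j}\, G^{2j+i}$ with
$W_{i,j} = -\binom{-k}{i} s^{-i} b_j^{(i)} (\pi/2)^{2j+i}$, where
$b_j^{(i)}$ is the coefficient of $z^{2j+i}$ in $\tan(z)^i$
($b_0^{(i)} = 1$, $b_1^{(i)} = i/3$, $b_2^{(i)} = i(5i+7)/90$).  We
read the sign prefactor as $-1$ times the generalized binomial
coefficient $\binom{-k}{i} = (-1)^i\binom{k+i-1}{i}$, which makes the
$i = 1$ weight positive and the truncated cdf increasing — the only
reading under which the expansion matches the closed form.

Two implementation paths exist on purpose.  `ltg_tan_coeff` computes
$b_j^{(i)}$ in exact rational arithmetic (tangent numbers from the
Entringer recurrence, reduced fraction convolution) and raises an
explicit depth error once a numerator or denominator would leave the
exactly representable integer range, rather than silently losing
exactness.  The weights path (`ltg_expg_weights`, `ltg_cdf_series`)
uses floating point with log-magnitude/sign bookkeeping so extreme $k$
cannot overflow, and has no depth limit.

The outer series converges only where $\tan(\pi G/2) < s$, i.e.
$G < (2/\pi)\arctan s$; at truncation $25 \times 25$ the agreement with
the closed form is below $10^{-6}$ on $G \le 1/2$ for moderate
$(k, s)$, and it diverges beyond the region — the closed forms are the
production path everywhere, the series an analytic cross-check.  The
corresponding mgf rearrangement is *purely formal* for unbounded
baselines: the exp-G generating function decays only polynomially in
its power parameter while the tangent coefficients do not decay at the
evaluation radius, so the double series diverges with truncation depth
for every positive argument (and for negative arguments once
$i \ge |t|/\beta + 1$).  `ltg_mgf_series` is retained so that this
divergence is inspectable; `ltg_mgf` (quadrature) is the numerical
path.

Order statistics use the log-space product form
$f_{i:n} = K f F^{i-1}(1-F)^{n-i}$ — an exact finite rearrangement of
the alternating binomial sum, which is also implemented
(`method = "binomial"`) purely as a cross-check; the infinite
triple-series rearrangement of the literature is documented but not a
computation path.

## Estimation

`ltg_fit` maximizes the log-likelihood in log-parameter space with
multiple starts: a Latin hypercube (default 20 points) over data-driven
log-ranges — generator shape $k \in [0.05, 10]$ and scale
$s \in [0.01, 50]$, baseline shapes in $[0.3, 5]$, baseline
scales/rates bracketed by sample quantiles — plus two deterministic
anchors, each polished by bounded quasi-Newton (L-BFGS-B) and a
Nelder-Mead/L-BFGS-B cycle.  Multi-start is not a luxury here.  The
$(s, k)$ pair is weakly identified: along a ridge with $k, s \to
\infty$ at fixed $k/s$ the family degenerates to the limit
$F = 1 - e^{-c \tan(\pi G/2)}$, and sample likelihoods often keep
climbing negligibly toward that boundary.  The optimizer therefore
works inside a generous compact box (the start ranges widened by a
factor of 100 on each side in log space); estimates that press against
the box are genuine features of the flat ridge, not optimizer
failures, and show up as the enormous biases and MSEs for $k$ and $s$
that estimator-quality studies of this family report.

Standard errors come from the observed information — the negative
Hessian of the log-likelihood at the optimum, by central finite
differences with step control — inverted exactly when possible and by
Moore–Penrose pseudo-inverse (with a warning) when near-singular.  The
printed analytic score expressions for this family contain typesetting
inconsistencies, so the numeric gradient/Hessian of the *verified*
log-likelihood is the safer contract.  Wald intervals are
$\hat\theta \pm z_{(1+\gamma)/2}\,\mathrm{se}$ on the natural scale.
Parameters can be pinned with `fixed =` (useful for well-identified
sub-models and for coverage experiments).

## Goodness of fit

`ltg_gof` reports $-\hat\ell$, AIC, BIC, HQIC and the corrected AIC
$\mathrm{AIC} + 2p(p+1)/(n-p-1)$ (the convention under which the
published comparison tables back-solve exactly; what those tables label
"$-2\hat\ell$" is in fact $-\hat\ell$, and the package labels it
honestly).  W\* and A\* follow the Chen–Balakrishnan procedure: map the
plug-in probabilities to normal scores, standardize by their sample
mean and standard deviation, map back to the unit interval, then apply
the Cramér–von Mises and Anderson–Darling formulas with small-sample
factors $(1 + 0.5/n)$ and $(1 + 0.75/n + 2.25/n^2)$.  The plain
untransformed variant is available (`transform = "none"`); only the
transformed one reproduces the published glass-fibre values, while the
flood data agree under both.  K-S p-values use the parameters-known
asymptotic Kolmogorov distribution, the convention of the comparison
tables being reproduced; a parametric-bootstrap p-value
(`bootstrap = TRUE`) exists for honest testing under estimated
parameters but is off by default.  Ties in the data are handled by the
right/left bracketing of the empirical cdf in the K-S statistic.

## The simulation study

`ltg_sim_study` draws each replicate by exact inverse transform,
refits with the same multi-start machinery, and tabulates bias, MSE,
empirical SD, coverage probability and average Wald width per
parameter and sample size, with per-replicate seeds drawn up front
from the master seed so any cell is independently reproducible.
Replicates without a converged fit or a usable standard error are
excluded and counted; cells with more than 20% exclusions are flagged.
The nominal interval level is 0.95 by default (the literature's
studies do not state theirs; 0.95 is the universal convention and it
is configurable).

What the generator emulates: complete i.i.d. samples from the exact
model, under the published scenario parameter sets (e.g.
$k = 0.2, s = 0.5, b = 0.8, a = 1.2$) and sample sizes 50–500.  What
it does not: censoring, covariates, measurement rounding,
contamination — so passing tests demonstrate estimator behavior under
the model, not robustness.  Because of the $(s,k)$ ridge, cell values
for $k$ and $s$ depend strongly on optimizer constraints and starting
strategies (unstated in the literature); the reproducible scientific
content is the *trend* — bias magnitudes and MSEs of the baseline
parameters fall as $n$ grows — and that is what the test suite
asserts, at 200 replicates with fixed seeds.  At moderate $n$ the
estimate distribution is heavy-tailed (occasional ridge excursions),
so SD-based calibration summaries are outlier-dominated; coverage,
which is robust to outliers, is the calibration check the suite uses,
and it is nominal for the well-identified pinned-$s$ LT-E sub-model
(400 replicates at $n = 500$).

Problem sizes used by the test suite were chosen to keep the full run
in minutes while leaving every assertion statistically comfortable:
200 replicates for the trend study, 400 for coverage, 20 replicates at
$n = 5000$ for 3-standard-error parameter recovery, $10^4$–$10^6$
draws for Monte Carlo cross-checks of moments and sampling.

## Known limitations

* No censored or truncated likelihood contributions; complete samples
  only.
* The $(s, k)$ ridge means generator-parameter estimates (and their
  Wald intervals) can be practically meaningless in small samples even
  when the fitted *distribution* is excellent; compare sub-models by
  fit statistics, not by generator-parameter values.
* K-S p-values ignore parameter estimation by default (see above).
* The exp-G series is a bounded-region cross-check, not an evaluation
  method, and the mgf series is formal only.
* The benchmark tables being reproduced print one internally
  inconsistent row (a parameter row that does not evaluate to its own
  published likelihood); the package reproduces every reproducible
  quantity and documents the discrepancy in its tests rather than
  papering over it.
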