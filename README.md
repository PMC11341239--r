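# ltgfam — the Lomax-tangent generalized family of distributions

`ltgfam` implements the Lomax-tangent generalized (LT-G) family of
lifetime distributions for reliability, hydrological and strength-of-
materials data.  It is aimed at analysts who need flexible parametric
hazard shapes — increasing, decreasing, unimodal, bathtub, even bimodal
densities — from a single four-parameter (or three-parameter) model,
together with the full maximum-likelihood / goodness-of-fit / Monte
Carlo workflow that papers in the distribution-theory literature report.

## The family

Take any baseline distribution with cdf G(x) and density g(x), and pass
it through a Lomax generator with the tangent link
W[G] = tan(πG(x)/2):

    F(x) = 1 − [1 + tan(πG(x)/2) / s]^(−k),        s > 0, k > 0

    f(x) = (πk / 2s) · g(x) · sec²(πG(x)/2) · [1 + tan(πG(x)/2)/s]^(−k−1)

The quantile function is closed form,

    Q(u) = G⁻¹( (2/π) · arctan( s·[(1−u)^(−1/k) − 1] ) ),

so random variates come from exact inverse-transform sampling.  Four
baselines are shipped: Weibull (sub-model **LT-W**, parameters b shape,
a scale), one-parameter gamma (**LT-Ga**), Rayleigh (**LT-R**) and
exponential (**LT-E**).

The package provides:

* `dltg`, `pltg`, `qltg`, `rltg`, `hltg` — density, cdf/survival,
  quantile, random generation, hazard, all evaluated in log space so the
  upper tail (where tan(πG/2) overflows) stays accurate;
* `ltg_fit` — multi-start maximum likelihood with observed-information
  standard errors, returning a fitted-model object with `print`,
  `summary`, `coef`, `vcov`, `logLik`, `confint`, `plot`, `simulate`,
  `residuals` methods;
* `ltg_gof` — the model-comparison battery: −ℓ̂, AIC/BIC/HQIC/corrected
  AIC, Cramér–von Mises W\* and Anderson–Darling A\* (Chen–Balakrishnan
  modification), Kolmogorov–Smirnov with p-value, plus `ltg_ttt` for the
  total-time-on-test diagnostic;
* `ltg_sim_study` — Monte Carlo estimator-quality study (bias, MSE,
  coverage probability, average Wald-interval width across sample
  sizes);
* series machinery (`ltg_tan_coeff`, `ltg_expg_weights`,
  `ltg_cdf_series`, `dltg_order`) — the exp-G expansion of the cdf with
  exact-rational tangent-power coefficients, and order-statistic
  densities;
* moments (`ltg_moment`, `ltg_moments`, `ltg_mgf`) and shape analysis
  (`ltg_critical_points`) for densities and hazard rates;
* two classic benchmark data sets via `ltg_data`: the 72 Wheaton River
  flood-peak exceedances and the 63 glass-fibre strengths;
* a command-line front end (`exec/ltg`) with `fit`, `gof`, `sample`,
  `describe`, `simulate` and `plot` subcommands.

## Worked example: glass-fibre strengths

```r
library(ltgfam)
fit <- ltg_fit(ltg_data("glass_fibre"), "weibull", seed = 1)
summary(fit)
#> Lomax-tangent weibull maximum-likelihood fit
#> n = 63, log-likelihood = -11.0119, AIC = 30.0238
#> 95% Wald intervals; 22/22 starts converged
#>
#>   estimate     se    lower  upper
#> k   0.7566 0.4265 -0.07943  1.593
#> s   7.5440 7.8510 -7.84200 22.930
#> b   3.8280 1.0570  1.75700  5.899
#> a   1.1860 0.1469  0.89800  1.474

ltg_gof(fit)
#> Goodness of fit: LT-W  (n = 63 , p = 4 )
#> -loglik     AIC     BIC    HQIC    CAIC      W*      A*     K-S p-value
#> 11.0119 30.0238 38.5964 33.3954 30.7135  0.0754  0.4332  0.0901  0.6865
```

The fitted LT-W says the fibre strengths are left-skewed
(`ltg_moments(fit$dist)` gives skewness −0.91) with median strength
1.56; the small W\*/A\*/K-S values and the K-S p-value of 0.69 say the
four-parameter LT-W describes the 63 strengths well.  The wide Wald
intervals on (k, s) are real: the generator pair is weakly identified
(a long flat likelihood ridge), which is why `ltg_fit` is multi-start
by default.

The same call with `ltg_data("wheaton")` reproduces the flood-data
analysis: −ℓ̂ = 247.12, AIC = 502.24, BIC = 511.35, K-S = 0.054 with
p = 0.98 — an excellent fit to a strongly right-skewed sample
(`ltg_describe(ltg_data("wheaton"))$skewness` ≈ 1.5).

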