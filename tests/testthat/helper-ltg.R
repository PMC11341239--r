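# Shared fixtures and independent oracles.

# parameter sets spanning the simulation-study scenarios (LT-W) plus one
# case per other baseline; used for integration / round-trip sweeps
ltg_test_cases <- function() {
  list(
    ltg("weibull", k = 0.2, s = 0.5, xi = c(b = 0.8, a = 1.2)),
    ltg("weibull", k = 0.8, s = 1.2, xi = c(b = 1.5, a = 1.8)),
    ltg("weibull", k = 1.5, s = 1.8, xi = c(b = 2.1, a = 2.6)),
    ltg("weibull", k = 1.1, s = 0.7, xi = c(b = 3.0, a = 3.5)),
    ltg("weibull", k = 2, s = 2, xi = c(b = 2, a = 1)),
    ltg("weibull", k = 2.9651, s = 13.7781, xi = c(b = 0.8301, a = 13.4326)),
    ltg("exponential", k = 1, s = 1, xi = c(beta = 1)),
    ltg("exponential", k = 0.6, s = 2.5, xi = c(beta = 0.4)),
    ltg("gamma", k = 1.3, s = 0.8, xi = c(beta = 2)),
    ltg("gamma", k = 0.7, s = 1.5, xi = c(beta = 0.9)),
    ltg("rayleigh", k = 0.5, s = 0.9, xi = c(beta = 1.4)),
    ltg("rayleigh", k = 2.2, s = 3.0, xi = c(beta = 0.3))
  )
}

# independent quantile oracle: bracketing bisection on the cdf
bisect_quantile <- function(fun, u, lower = 0, upper = 1e6, iter = 200) {
  lo <- lower + 1e-300; hi <- upper
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (fun(mid) < u) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# central-difference derivative with an h-sweep, returning the best match
num_deriv <- function(fun, x, hs = 10^seq(-4, -7)) {
  vapply(x, function(xx) {
    est <- vapply(hs, function(h) (fun(xx + h) - fun(xx - h)) / (2 * h),
                  numeric(1))
    stats::median(est)
  }, numeric(1))
}

# total probability mass by adaptive quadrature over the support
total_mass <- function(d, upper = NULL) {
  if (is.null(upper)) upper <- qltg(1 - 1e-12, d)
  stats::integrate(function(x) dltg(x, d), 0, upper,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}
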