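test_that("raw moments: normalization, dual quadrature routes, Monte Carlo", {
  d <- ltg("weibull", k = 2, s = 2, xi = c(b = 2, a = 1))
  expect_identical(ltg_moment(d, 0), 1)
  # u-scale quadrature against an independent x-scale quadrature
  for (r in 1:4) {
    mx <- integrate(function(x) x^r * dltg(x, d), 0, qltg(1 - 1e-12, d),
                    rel.tol = 1e-10, subdivisions = 500L)$value
    expect_equal(ltg_moment(d, r), mx, tolerance = 1e-6,
                 label = paste("moment order", r))
  }
  # LT-E first moment against the mean of 1e6 simulated draws
  de <- ltg("exponential", k = 1, s = 1, xi = c(beta = 1))
  x <- rltg(1e6, de, seed = 31)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(ltg_moment(de, 1) - mean(x)), 4 * se)
})

test_that("skewness/kurtosis obey moment identities and Monte Carlo", {
  d <- ltg("weibull", k = 2, s = 2, xi = c(2, 1))
  m <- ltg_moments(d)
  expect_gte(m$variance, 0)
  # Pearson inequality
  expect_gte(m$kurtosis, m$skewness^2 + 1)
  expect_equal(m$excess_kurtosis, m$kurtosis - 3)
  x <- rltg(1e6, d, seed = 32)
  mc_sk <- mean((x - mean(x))^3) / sd(x)^3
  mc_ku <- mean((x - mean(x))^4) / var(x)^2
  expect_equal(m$skewness, mc_sk, tolerance = 0.02)
  expect_equal(m$kurtosis, mc_ku, tolerance = 0.02)
  # a numerically symmetrized density has zero skewness: X and -X mixture
  # via the reflection identity mu3(central) of symmetric combination
  sym_m3 <- function(dd) {
    mu <- ltg_moment(dd, 1)
    f <- function(x) ((x - mu)^3 + (mu - x)^3) / 2 * dltg(x, dd)
    integrate(f, 0, qltg(1 - 1e-12, dd), rel.tol = 1e-9)$value
  }
  expect_equal(sym_m3(d), 0, tolerance = 1e-8)
})

test_that("moment surface is finite over a baseline parameter box", {
  # skewness/kurtosis over a (b, a) grid: no NaN, smooth trend
  for (b in c(0.8, 1.5, 3)) for (a in c(0.5, 2)) {
    m <- ltg_moments(ltg("weibull", k = 1.2, s = 1.5, xi = c(b, a)),
                     rel.tol = 1e-8)
    expect_true(is.finite(m$skewness) && is.finite(m$kurtosis),
                label = sprintf("b=%g a=%g", b, a))
  }
})

test_that("mgf: exact at zero, derivative identities, divergence signalled", {
  d <- ltg("exponential", k = 2, s = 2, xi = c(beta = 1.5))
  expect_identical(ltg_mgf(d, 0), 1)
  h <- 1e-4
  d1 <- (ltg_mgf(d, h) - ltg_mgf(d, -h)) / (2 * h)
  expect_equal(d1, ltg_moment(d, 1), tolerance = 1e-6)
  d2 <- (ltg_mgf(d, h) - 2 + ltg_mgf(d, -h)) / h^2
  expect_equal(d2, ltg_moment(d, 2), tolerance = 1e-5)
  # the heavy-side argument region diverges and says so
  expect_error(ltg_mgf(d, 1e4), "converge")
  # the formal exp-G series rearrangement is non-convergent here: the
  # truncated sum departs from the quadrature value as depth grows
  q <- ltg_mgf(d, -3)
  err <- vapply(c(6, 12, 18), function(tr)
    abs(ltg_mgf_series(d, -3, tr, tr) - q), numeric(1))
  expect_true(all(diff(err) > 0))
})

test_that("density critical points: bimodal Rayleigh case, monotone case,
           first-order and curvature conditions", {
  # Rayleigh sub-model in its bimodal region: two maxima, one minimum
  dr <- ltg("rayleigh", k = 0.0968, s = 0.292, xi = c(beta = 1))
  cp <- ltg_critical_points(dr, "density", bracket = c(1e-3, 4))
  expect_identical(sum(cp$type == "maximum"), 2L)
  expect_identical(sum(cp$type == "minimum"), 1L)
  # grid-scan oracle: modality from direct density evaluation
  xs <- seq(1e-3, 4, length.out = 4000)
  sgn <- sign(diff(dltg(xs, dr)))
  expect_identical(sum(sgn[-1] != sgn[-length(sgn)]), 3L)
  # each root satisfies the first-order condition; numeric curvature
  # agrees with the reported classification
  expect_lt(max(abs(cp$deriv)), 1e-8)
  for (r in seq_len(nrow(cp))) {
    lam <- num_deriv(function(x) ltgfam:::.dlogf_dx(dr, x), cp$x[r])
    expect_identical(unname(lam < 0), cp$type[r] == "maximum")
  }
  # monotone-decreasing density: no interior critical points
  dm <- ltg("weibull", k = 0.2, s = 0.5, xi = c(0.8, 1.2))
  expect_identical(nrow(ltg_critical_points(dm, "density")), 0L)
})

test_that("analytic density derivative matches finite differences and
           empirical monotonicity between critical points", {
  d <- ltg("weibull", k = 1.5, s = 1.8, xi = c(2.1, 2.6))
  xs <- qltg(seq(0.1, 0.9, length.out = 15), d)
  expect_equal(ltgfam:::.dlogf_dx(d, xs),
               num_deriv(function(x) dltg(x, d, log = TRUE), xs),
               tolerance = 1e-6)
  expect_equal(ltgfam:::.dlogh_dx(d, xs),
               num_deriv(function(x) hltg(x, d, log = TRUE), xs),
               tolerance = 1e-6)
  cp <- ltg_critical_points(d, "density")
  brk <- c(qltg(1e-4, d), sort(cp$x), qltg(1 - 1e-4, d))
  for (seg in seq_len(length(brk) - 1)) {
    gx <- seq(brk[seg] + 1e-6, brk[seg + 1] - 1e-6, length.out = 50)
    fd <- diff(dltg(gx, d))
    expect_true(all(fd > 0) || all(fd < 0),
                label = paste("monotone between critical points, segment", seg))
  }
})

test_that("hazard shape analysis distinguishes increasing from non-monotone", {
  # glass-fibre-like LT-W fit region: increasing hazard, no critical point
  di <- ltg("weibull", k = 0.755, s = 7.522, xi = c(3.8308, 1.1863))
  expect_identical(nrow(ltg_critical_points(di, "hazard")), 0L)
  xs <- seq(0.3, 2.5, length.out = 200)
  expect_true(all(diff(hltg(xs, di)) > 0))
  # Wheaton-fit region: hazard rises then falls (upside-down bathtub)
  du <- ltg("weibull", k = 0.1927, s = 0.0669, xi = c(1.5858, 7.0293))
  cp <- ltg_critical_points(du, "hazard")
  expect_gte(nrow(cp), 1L)
  expect_true("maximum" %in% cp$type)
})
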