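test_that("log-likelihood matches its closed form and the published fit", {
  gf <- ltg_data("glass_fibre")
  # printed glass-fibre MLEs reproduce the published -loglik of 11.01
  expect_lt(abs(ltg_loglik(c(0.755, 7.5220, 3.8308, 1.1863), gf, "weibull") +
                  11.01), 0.05)
  # term-for-term closed form of the likelihood
  th <- c(k = 0.9, s = 1.4, b = 1.7, a = 1.5)
  G <- pweibull(gf, th["b"], th["a"])
  n <- length(gf)
  direct <- n * log(th["k"]) + n * log(pi) +
    sum(dweibull(gf, th["b"], th["a"], log = TRUE)) -
    (th["k"] + 1) * sum(log(tan(pi * G / 2) / th["s"] + 1)) +
    sum(log(1 / cos(pi * G / 2)^2)) - n * log(th["s"]) - n * log(2)
  expect_equal(ltg_loglik(th, gf, "weibull"), unname(direct),
               tolerance = 1e-10)
  # single observation at the baseline median with neutral generator
  expect_equal(ltg_loglik(c(1, 1, 1), log(2), "exponential"),
               log(pi / 4 * dexp(log(2), 1)), tolerance = 1e-12)
  # equals the sum of logs of the numerically differentiated cdf
  d <- ltg("weibull", th["k"], th["s"], th[c("b", "a")])
  fd <- vapply(gf, function(xx)
    (pltg(xx + 5e-5, d) - pltg(xx - 5e-5, d)) / 1e-4, numeric(1))
  expect_equal(ltg_loglik(th, gf, "weibull"), sum(log(fd)), tolerance = 1e-6)
  expect_error(ltg_loglik(c(1, 1, 1), numeric(0), "exponential"), "nonempty")
})

test_that("likelihood is invariant to the log-reparameterization", {
  gf <- ltg_data("glass_fibre")
  lth <- c(-0.2, 0.5, 1.1, 0.2)
  expect_identical(ltg_loglik(exp(lth), gf, "weibull"),
                   ltg_loglik(exp(lth + 0), gf, "weibull"))
  # evaluating at matched natural/log points gives the same value
  th <- exp(lth)
  expect_equal(ltg_loglik(th, gf, "weibull"),
               ltg_loglik(exp(log(th)), gf, "weibull"), tolerance = 0)
})

test_that("maximum likelihood matches the published applications", {
  fit_w <- ltg_fit(ltg_data("wheaton"), "weibull", seed = 1)
  expect_true(fit_w$converged)
  expect_lte(-fit_w$loglik, 247.13)      # at least as good as published
  fit_g <- ltg_fit(ltg_data("glass_fibre"), "weibull", seed = 1)
  expect_lte(-fit_g$loglik, 11.02)
  # glass-fibre estimates land on the published point
  expect_equal(unname(fit_g$estimates),
               c(0.755, 7.5220, 3.8308, 1.1863), tolerance = 0.02)
  # the returned maximum beats every start (best-endpoint contract)
  expect_gte(fit_w$n_starts_converged, 1L)
})

test_that("parameter recovery on simulated LT-E data", {
  d0 <- ltg("exponential", k = 1, s = 1, xi = c(beta = 1))
  x <- rltg(5000, d0, seed = 41)
  fit <- ltg_fit(x, "exponential", n_starts = 10, seed = 1)
  expect_true(fit$converged)
  for (p in c("k", "s", "beta")) {
    expect_lt(abs(fit$estimates[p] - 1), 3 * fit$se[p],
              label = paste("recovery of", p))
  }
})

test_that("fit is deterministic given a seed and consistent as n grows", {
  d0 <- ltg("exponential", k = 1, s = 1, xi = c(beta = 1))
  x <- rltg(300, d0, seed = 55)
  f1 <- ltg_fit(x, "exponential", seed = 3)
  f2 <- ltg_fit(x, "exponential", seed = 3)
  expect_identical(f1$estimates, f2$estimates)
  # median parameter error does not grow from n = 200 to n = 2000
  err <- sapply(c(200, 2000), function(n) {
    e <- sapply(1:5, function(r) {
      xr <- rltg(n, d0, seed = 100 * n + r)
      fr <- ltg_fit(xr, "exponential", n_starts = 6, seed = r)
      abs(fr$estimates - 1)
    })
    median(e)
  })
  expect_lte(err[2], err[1])
})

test_that("observed information gives a usable curvature summary", {
  gf <- ltg_data("glass_fibre")
  fit <- ltg_fit(gf, "weibull", seed = 1)
  info <- ltg_obs_info(fit$estimates, gf, "weibull")
  # gradient at the MLE is numerically zero
  g <- pracma::grad(function(th) {
    v <- suppressWarnings(ltg_loglik(th, gf, "weibull"))
    if (!is.finite(v)) -1e10 else v
  }, fit$estimates)
  expect_lt(sqrt(sum(g^2)), 1e-3 * fit$n)
  # covariance is symmetric positive semidefinite with se = sqrt(diag)
  expect_equal(info$vcov, t(info$vcov), tolerance = 1e-8)
  expect_true(all(eigen(info$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_equal(unname(info$se[fit$free]), unname(sqrt(diag(info$vcov))),
               tolerance = 1e-12)
})

test_that("Wald intervals have the textbook form", {
  fit <- ltg_fit(ltg_data("glass_fibre"), "weibull", seed = 1)
  ci <- confint(fit, level = 0.95)
  z <- qnorm(0.975)
  expect_equal(ci[, "upper"] - ci[, "lower"], 2 * z * fit$se[fit$free],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(attr(ci, "width")), unname(2 * z * fit$se[fit$free]))
  # se = 1, est = 0 gives (-1.96, 1.96) and width 3.92
  toy <- fit
  toy$estimates[] <- 0; toy$se[] <- 1
  ci0 <- confint(toy, level = 0.95)
  expect_equal(unname(ci0[1, ]), c(-z, z))
  expect_equal(unname(attr(ci0, "width")[1]), 2 * z)
})

test_that("fixed-parameter fits hold the constraint", {
  d0 <- ltg("exponential", k = 1, s = 1, xi = c(beta = 1))
  x <- rltg(400, d0, seed = 77)
  fit <- ltg_fit(x, "exponential", fixed = c(s = 1), n_starts = 6, seed = 1)
  expect_identical(unname(fit$estimates["s"]), 1)
  expect_true(is.na(fit$se["s"]))
  expect_identical(fit$free, c("k", "beta"))
})

test_that("data validation rejects out-of-support values by index", {
  expect_error(ltg_fit(c(1, 2, -3, 0.5, 0), "weibull"),
               "indices: 3, 5")
  expect_error(ltg_fit(numeric(0), "weibull"), "nonempty")
  expect_error(ltg_fit(c(1, NA, 2), "weibull"), "missing")
})

test_that("fit object supports the standard modelling verbs", {
  fit <- ltg_fit(ltg_data("glass_fibre"), "weibull", seed = 1)
  expect_identical(coef(fit), fit$estimates)
  expect_equal(AIC(fit), 2 * 4 - 2 * fit$loglik)
  expect_identical(dim(vcov(fit)), c(4L, 4L))
  s <- summary(fit)
  expect_s3_class(s, "summary.ltg_fit")
  expect_identical(rownames(s$table), c("k", "s", "b", "a"))
  r <- residuals(fit)
  expect_identical(length(r), fit$n)
  expect_lt(abs(mean(r)), 0.5)   # roughly standard normal under the model
  sim <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(dim(sim), c(fit$n, 2L))
  js <- ltg_fit_json(fit)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$loglik, fit$loglik)
  expect_identical(parsed$baseline, "weibull")
})
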