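#' Information criteria from a maximized likelihood
#'
#' Given the negative maximized log-likelihood \eqn{-\hat\ell}, sample
#' size `n` and number of fitted parameters `p`:
#' \deqn{AIC = 2(-\hat\ell) + 2p, \quad BIC = 2(-\hat\ell) + p\ln n,}
#' \deqn{HQIC = 2(-\hat\ell) + 2p\ln\ln n, \quad
#'   CAIC = AIC + \frac{2p(p+1)}{n - p - 1},}
#' where CAIC is the corrected AIC (AICc).
#'
#' @param neg_loglik Negative maximized log-likelihood \eqn{-\hat\ell}.
#' @param n Sample size.
#' @param p Number of fitted parameters.
#' @return Named vector `c(aic, bic, hqic, caic)`; `caic` is `NA` with a
#'   warning when `n <= p + 1`.
#' @export
ltg_info_criteria <- function(neg_loglik, n, p) {
  aic <- 2 * neg_loglik + 2 * p
  bic <- 2 * neg_loglik + p * log(n)
  hqic <- 2 * neg_loglik + 2 * p * log(log(n))
  caic <- if (n > p + 1) aic + 2 * p * (p + 1) / (n - p - 1) else {
    warning("corrected AIC undefined for n <= p + 1"); NA_real_
  }
  c(aic = aic, bic = bic, hqic = hqic, caic = caic)
}

#' One-sample Kolmogorov-Smirnov test against an LT-G distribution
#'
#' \eqn{D_n = \max_i \max\{i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n\}},
#' with the p-value from the asymptotic Kolmogorov distribution
#' \eqn{P(\sqrt{n} D_n > \lambda) = 2\sum_{j\ge1} (-1)^{j-1} e^{-2j^2\lambda^2}}.
#' Parameters are treated as known (the conventional plug-in practice
#' for fitted-model comparison tables); for an honest test under
#' estimated parameters use `bootstrap = TRUE`, which re-fits on
#' parametric resamples.
#'
#' @param x Data vector (nonempty; ties allowed).
#' @param d An `"ltg"` object (typically at fitted parameters).
#' @param bootstrap If `TRUE`, compute a parametric-bootstrap p-value.
#' @param B Number of bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List with `statistic` and `p.value`.
#' @export
ltg_ks_test <- function(x, d, bootstrap = FALSE, B = 200, seed = 1L) {
  if (!length(x)) stop("'x' must be a nonempty data vector")
  n <- length(x)
  Fx <- sort(pltg(sort(x), d))
  i <- seq_len(n)
  D <- max(pmax(i / n - Fx, Fx - (i - 1) / n))
  if (!bootstrap) {
    pv <- .kolmogorov_sf(sqrt(n) * D)
  } else {
    set.seed(seed)
    fit0 <- ltg_fit(x, d$baseline$name, n_starts = 8, seed = seed)
    Db <- replicate(B, {
      xb <- rltg(n, d)
      fb <- ltg_fit(xb, d$baseline$name, n_starts = 8, seed = seed)
      if (!isTRUE(fb$converged)) return(NA_real_)
      Fb <- sort(pltg(sort(xb), fb$dist))
      max(pmax(i / n - Fb, Fb - (i - 1) / n))
    })
    pv <- mean(Db >= D, na.rm = TRUE)
  }
  list(statistic = D, p.value = pv)
}

# upper tail of the Kolmogorov distribution, 2 sum (-1)^{j-1} exp(-2 j^2 t^2)
.kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))))
}

#' Cramer-von Mises and Anderson-Darling statistics (W*, A*)
#'
#' Computes the modified statistics used for comparing fitted lifetime
#' models.  With `transform = "chen-balakrishnan"` (the default, and the
#' convention behind published comparison tables) the plug-in
#' probabilities \eqn{u_i = F(x_i;\hat\Theta)} are first mapped to
#' normal scores \eqn{e_i = \Phi^{-1}(u_i)}, standardized by their
#' sample mean and standard deviation, and mapped back,
#' \eqn{v_i = \Phi((e_i - \bar e)/s_e)}; the statistics are then
#' \deqn{W^2 = \sum_i \left(v_{(i)} - \frac{2i-1}{2n}\right)^2 + \frac{1}{12n}, \qquad
#'   A^2 = -n - \frac{1}{n}\sum_i (2i-1)\left[\ln v_{(i)} + \ln(1 - v_{(n+1-i)})\right],}
#' with small-sample factors \eqn{W^* = W^2(1 + 0.5/n)} and
#' \eqn{A^* = A^2(1 + 0.75/n + 2.25/n^2)}.  `transform = "none"` applies
#' the same formulas directly to the \eqn{u_{(i)}}.
#'
#' @param x Data vector.
#' @param d An `"ltg"` object at the fitted parameters.
#' @param transform `"chen-balakrishnan"` (default) or `"none"`.
#' @return Named vector `c(w_star, a_star)`.
#' @export
ltg_cvm_ad <- function(x, d, transform = c("chen-balakrishnan", "none")) {
  transform <- match.arg(transform)
  n <- length(x)
  u <- pltg(sort(x), d)
  if (any(u <= 0 | u >= 1)) {
    warning("fitted probabilities at 0 or 1 clamped for W*/A*")
    u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  }
  if (transform == "chen-balakrishnan") {
    e <- stats::qnorm(u)
    u <- sort(stats::pnorm((e - mean(e)) / stats::sd(e)))
    u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  } else {
    u <- sort(u)
  }
  i <- seq_len(n)
  W2 <- sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
  c(w_star = W2 * (1 + 0.5 / n), a_star = A2 * (1 + 0.75 / n + 2.25 / n^2))
}

#' Scaled total-time-on-test (TTT) transform
#'
#' Points \eqn{(i/n,\; T_i/T_n)} with
#' \eqn{T_i = \sum_{j \le i} x_{(j)} + (n-i) x_{(i)}}, prepended with the
#' origin.  A concave curve diagnoses an increasing hazard rate, a convex
#' curve a decreasing one, and an S shape a bathtub.
#'
#' @param x Nonnegative data vector with a positive total.
#' @return Data frame with columns `u` (\eqn{i/n}) and `ttt`
#'   (\eqn{T_i/T_n}), including the endpoints (0,0) and (1,1).
#' @export
ltg_ttt <- function(x) {
  if (!length(x) || any(x < 0)) stop("'x' must be nonnegative")
  if (sum(x) == 0) stop("TTT transform undefined for all-zero data")
  xs <- sort(x)
  n <- length(xs)
  Ti <- cumsum(xs) + (n - seq_len(n)) * xs
  data.frame(u = c(0, seq_len(n) / n), ttt = c(0, Ti / Ti[n]))
}

#' Goodness-of-fit battery for a fitted LT-G model
#'
#' Bundles the model-comparison report used for fitted lifetime models:
#' \eqn{-\hat\ell}, the four information criteria of
#' [ltg_info_criteria()], the Chen--Balakrishnan-modified
#' Cramer--von Mises \eqn{W^*} and Anderson--Darling \eqn{A^*}, and the
#' Kolmogorov--Smirnov statistic with its (parameters-known) p-value.
#'
#' @param fit An `"ltg_fit"` object.
#' @param transform Passed to [ltg_cvm_ad()].
#' @return Object of class `"ltg_gof"`: a list with `model`,
#'   `neg_loglik`, `aic`, `bic`, `hqic`, `caic`, `w_star`, `a_star`,
#'   `ks`, `ks_pvalue`, `n`, `p`.
#' @export
ltg_gof <- function(fit, transform = "chen-balakrishnan") {
  stopifnot(inherits(fit, "ltg_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  n <- fit$n
  p <- length(fit$free)
  ic <- ltg_info_criteria(-fit$loglik, n, p)
  wa <- ltg_cvm_ad(fit$data, fit$dist, transform = transform)
  ks <- ltg_ks_test(fit$data, fit$dist)
  structure(list(model = paste0("LT-", switch(fit$baseline,
                   weibull = "W", gamma = "Ga", rayleigh = "R",
                   exponential = "E")),
                 neg_loglik = -fit$loglik,
                 aic = unname(ic["aic"]), bic = unname(ic["bic"]),
                 hqic = unname(ic["hqic"]), caic = unname(ic["caic"]),
                 w_star = unname(wa["w_star"]), a_star = unname(wa["a_star"]),
                 ks = ks$statistic, ks_pvalue = ks$p.value,
                 n = n, p = p),
            class = "ltg_gof")
}

#' @export
print.ltg_gof <- function(x, digits = 4, ...) {
  cat("Goodness of fit:", x$model, " (n =", x$n, ", p =", x$p, ")\n")
  v <- c(`-loglik` = x$neg_loglik, AIC = x$aic, BIC = x$bic, HQIC = x$hqic,
         CAIC = x$caic, `W*` = x$w_star, `A*` = x$a_star, `K-S` = x$ks,
         `p-value` = x$ks_pvalue)
  print(round(v, digits))
  invisible(x)
}

#' Convert a goodness-of-fit report to a one-row data frame
#'
#' Shaped like a row of a model-comparison table (columns
#' model, -loglik, AIC, BIC, HQIC, CAIC, W*, A*, K-S, p-value).
#'
#' @param x An `"ltg_gof"` object.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.ltg_gof <- function(x, ...) {
  data.frame(model = x$model, neg_loglik = x$neg_loglik, aic = x$aic,
             bic = x$bic, hqic = x$hqic, caic = x$caic, w_star = x$w_star,
             a_star = x$a_star, ks = x$ks, ks_pvalue = x$ks_pvalue)
}
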