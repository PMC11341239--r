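#' Log-likelihood of an LT-G sub-model
#'
#' For a complete sample \eqn{x_1, \dots, x_n} the log-likelihood is
#' \deqn{\ell_n(\Theta) = n\log k + n\log\pi + \sum_i \log g(x_i;\xi)
#'   - (k+1)\sum_i \log\!\left(1 + \frac{\tan(\pi G(x_i;\xi)/2)}{s}\right)
#'   + \sum_i \log \sec^2\!\left(\frac{\pi G(x_i;\xi)}{2}\right)
#'   - n\log s - n\log 2,}
#' i.e. the sum of [dltg()] log-densities.  Observations with zero
#' density (outside the support) make the total `-Inf`, which the
#' optimizer treats as an invalid parameter region.
#'
#' @param params Full parameter vector `c(k, s, <baseline params>)`, or
#'   an `"ltg"` object.
#' @param x Data vector (nonempty).
#' @param baseline Baseline name; ignored when `params` is an `"ltg"`.
#' @return The log-likelihood (natural log).
#' @examples
#' gf <- ltg_data("glass_fibre")
#' ltg_loglik(c(0.755, 7.5220, 3.8308, 1.1863), gf, baseline = "weibull")
#' @export
ltg_loglik <- function(params, x, baseline = "weibull") {
  if (!length(x)) stop("'x' must be a nonempty data vector")
  d <- if (inherits(params, "ltg")) params else
    ltg(baseline, k = params[1], s = params[2], xi = params[-(1:2)])
  sum(dltg(x, d, log = TRUE))
}

# data-driven log-scale start ranges for each parameter
.start_ranges <- function(baseline, x) {
  gen <- rbind(k = c(0.05, 10), s = c(0.01, 50))
  bl <- switch(baseline$name,
    weibull = rbind(b = c(0.3, 5),
                    a = c(max(stats::quantile(x, 0.05), min(x[x > 0])),
                          3 * max(x))),
    gamma = rbind(beta = c(0.3 * mean(x), 3 * mean(x) + 1)),
    rayleigh = rbind(beta = c(0.2 / mean(x^2), 5 / mean(x^2))),
    exponential = rbind(beta = c(0.2 / mean(x), 5 / mean(x))))
  log(rbind(gen, bl))
}

#' Fit an LT-G sub-model by maximum likelihood
#'
#' Maximizes the log-likelihood over the positive orthant by
#' quasi-Newton search in log-parameter space, from multiple starting
#' points: a Latin hypercube over data-driven log-ranges plus fixed
#' heuristic starts.  Multi-start is essential here: the generator pair
#' \eqn{(s, k)} is weakly identified (the likelihood has a long flat
#' ridge), so single-start optimizers routinely stall on local optima.
#' The best endpoint is polished with Nelder--Mead/BFGS cycles.  Standard
#' errors come from the observed information (negative Hessian of the
#' log-likelihood at the optimum, differentiated numerically).
#'
#' @param x Positive data vector, or a one-column data frame.
#' @param baseline Baseline name, one of [ltg_baselines()].
#' @param n_starts Number of Latin-hypercube starts (default 20).
#' @param starts Optional matrix of additional starts, one row per
#'   start, columns in natural-parameter order `c(k, s, xi)`.
#' @param fixed Optional named vector of parameters to hold fixed, e.g.
#'   `c(s = 1)`; fixed parameters get `NA` standard errors.
#' @param seed Integer seed controlling the Latin hypercube (the fit is
#'   deterministic given `seed`).
#' @param level Confidence level stored for [confint()] and [summary()].
#' @param control Passed to [stats::optim()] for the BFGS stage.
#' @return Object of class `"ltg_fit"`: estimates, standard errors,
#'   covariance matrix, maximized log-likelihood, convergence flag,
#'   number of starts that converged, the fitted `"ltg"` distribution
#'   and the data.
#' @examples
#' \donttest{
#' fit <- ltg_fit(ltg_data("glass_fibre"), "weibull", seed = 1)
#' summary(fit)
#' }
#' @seealso [ltg_gof()] for the goodness-of-fit battery,
#'   [ltg_sim_study()] for estimator-quality simulations.
#' @export
ltg_fit <- function(x, baseline = "weibull", n_starts = 20, starts = NULL,
                    fixed = NULL, seed = 1L, level = 0.95,
                    control = list()) {
  cl <- match.call()
  if (is.data.frame(x)) x <- x[[1]]
  x <- as.numeric(x)
  if (!length(x)) stop("'x' must be a nonempty data vector")
  if (anyNA(x)) stop("'x' contains missing values")
  bl <- ltg_baseline(baseline)
  bad <- which(x <= bl$support[1])
  if (length(bad))
    stop("data must exceed the support lower bound ", bl$support[1],
         "; offending indices: ", paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "")

  pnames <- c("k", "s", bl$param_names)
  npar <- length(pnames)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% pnames))
      stop("'fixed' must be a named vector with names among: ",
           paste(pnames, collapse = ", "))
  }
  free <- setdiff(pnames, names(fixed))
  idx_free <- match(free, pnames)

  full_par <- function(theta_free) {
    p <- numeric(npar); names(p) <- pnames
    p[names(fixed)] <- fixed
    p[free] <- theta_free
    p
  }
  nll <- function(lth) {
    p <- full_par(exp(lth))
    # extreme exploratory parameter values can emit harmless NaN warnings
    v <- suppressWarnings(
      tryCatch(-ltg_loglik(p, x, baseline), error = function(e) Inf))
    if (!is.finite(v)) 1e10 else v
  }

  rng <- .start_ranges(bl, x)[idx_free, , drop = FALSE]
  set.seed(seed)
  lhs_pts <- lhs::randomLHS(max(n_starts, 1L), length(free))
  start_mat <- t(apply(lhs_pts, 1, function(u) rng[, 1] + u * (rng[, 2] - rng[, 1])))
  if (length(free) == 1L) start_mat <- matrix(start_mat, ncol = 1L)
  # heuristic anchors: neutral generator (k = s = 1) at mid-range baseline
  # values, and the range midpoint
  mid <- (rng[, 1] + rng[, 2]) / 2
  anchor <- mid
  anchor[free %in% c("k", "s")] <- 0
  start_mat <- rbind(start_mat, mid, anchor)
  if (!is.null(starts)) {
    starts <- as.matrix(starts)
    start_mat <- rbind(start_mat, log(starts[, idx_free, drop = FALSE]))
  }

  # box in log space: the (s, k) pair is only weakly identified and the
  # likelihood keeps climbing (negligibly) along a flat ridge toward a
  # degenerate limit; a generous compact box keeps estimates finite
  lb <- rng[, 1] - log(100)
  ub <- rng[, 2] + log(100)
  start_mat <- sweep(sweep(start_mat, 2, lb, pmax), 2, ub, pmin)
  best <- NULL; n_conv <- 0L
  for (r in seq_len(nrow(start_mat))) {
    o <- tryCatch(stats::optim(start_mat[r, ], nll, method = "L-BFGS-B",
                               lower = lb, upper = ub,
                               control = utils::modifyList(
                                 list(maxit = 300, factr = 1e4), control)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= 1e10) next
    n_conv <- n_conv + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    return(structure(list(call = cl, baseline = bl$name, converged = FALSE,
                          n_starts_used = nrow(start_mat), n = length(x),
                          message = "all starts failed"), class = "ltg_fit"))

  # polish: Nelder-Mead / L-BFGS-B cycle tightens the flat-ridge optimum
  p <- best$par
  for (it in 1:2) {
    o <- stats::optim(p, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-13))
    o <- tryCatch(stats::optim(pmin(pmax(o$par, lb), ub), nll,
                               method = "L-BFGS-B", lower = lb, upper = ub,
                               control = list(maxit = 500, factr = 1e3)),
                  error = function(e) o)
    improved <- o$value < best$value - 1e-10
    p <- o$par
    if (o$value <= best$value) best <- o
    if (!improved) break
  }
  theta <- exp(pmin(pmax(p, lb), ub))
  est <- full_par(theta)
  ll <- ltg_loglik(est, x, baseline)

  info <- ltg_obs_info(est, x, baseline = baseline, free = free)
  dist <- ltg(baseline, k = est["k"], s = est["s"], xi = est[-(1:2)])

  structure(list(call = cl, baseline = bl$name, estimates = est,
                 free = free, fixed = fixed,
                 se = info$se, vcov = info$vcov, loglik = ll,
                 n = length(x), converged = TRUE,
                 n_starts_used = nrow(start_mat), n_starts_converged = n_conv,
                 level = level, dist = dist, data = x),
            class = "ltg_fit")
}

#' Observed information and parameter covariance
#'
#' The observed information is the negative Hessian of the
#' log-likelihood at `params`, obtained by central finite differences
#' with step control ([pracma::hessian()]).  The covariance is its
#' inverse; if near-singular, a Moore--Penrose pseudo-inverse is used
#' with a warning.
#'
#' @param params Full named parameter vector `c(k, s, xi)`.
#' @param x Data vector.
#' @param baseline Baseline name.
#' @param free Names of the free parameters (defaults to all).
#' @return List with `info` (observed information over the free
#'   parameters), `vcov`, and `se` (full-length, `NA` for fixed or
#'   non-estimable entries).
#' @export
ltg_obs_info <- function(params, x, baseline = "weibull", free = NULL) {
  bl <- ltg_baseline(baseline)
  pnames <- c("k", "s", bl$param_names)
  if (is.null(names(params))) names(params) <- pnames[seq_along(params)]
  if (is.null(free)) free <- pnames
  th0 <- params[free]
  fn <- function(th) {
    p <- params; p[free] <- th
    v <- suppressWarnings(
      tryCatch(ltg_loglik(p, x, baseline), error = function(e) -Inf))
    if (!is.finite(v)) -1e10 else v
  }
  H <- tryCatch(pracma::hessian(fn, th0), error = function(e) NULL)
  se <- rep(NA_real_, length(params)); names(se) <- names(params)
  if (is.null(H) || any(!is.finite(H)))
    return(list(info = NULL, vcov = NULL, se = se))
  info <- -H
  dimnames(info) <- list(free, free)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(vc)) {
    warning("observed information is near-singular; ",
            "using Moore-Penrose pseudo-inverse")
    vc <- MASS::ginv(info)
    dimnames(vc) <- dimnames(info)
  }
  dg <- diag(vc)
  se[free] <- ifelse(dg >= 0, sqrt(dg), NA_real_)
  list(info = info, vcov = vc, se = se)
}

#' Wald confidence intervals for an LT-G fit
#'
#' `estimate +/- z_{(1+level)/2} * se` per free parameter.
#'
#' @param object An `"ltg_fit"`.
#' @param parm Parameters to report (default: all free).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix with `lower` and `upper` columns; attribute `width`
#'   holds the interval widths `2 z se`.
#' @export
confint.ltg_fit <- function(object, parm = NULL, level = object$level, ...) {
  if (!isTRUE(object$converged)) stop("fit did not converge")
  if (is.null(object$vcov)) stop("fit has no covariance matrix")
  if (is.null(parm)) parm <- object$free
  z <- stats::qnorm((1 + level) / 2)
  est <- object$estimates[parm]
  se <- object$se[parm]
  out <- cbind(lower = est - z * se, upper = est + z * se)
  rownames(out) <- parm
  attr(out, "width") <- 2 * z * se
  out
}

#' @export
print.ltg_fit <- function(x, digits = 4, ...) {
  cat("Lomax-tangent ", x$baseline, " fit (n = ", x$n, ")\n", sep = "")
  if (!isTRUE(x$converged)) {
    cat("  DID NOT CONVERGE: ", x$message, "\n")
    return(invisible(x))
  }
  print(signif(x$estimates, digits))
  cat("log-likelihood:", format(x$loglik, digits = digits + 2), "\n")
  invisible(x)
}

#' @export
summary.ltg_fit <- function(object, ...) {
  if (!isTRUE(object$converged)) return(object)
  ci <- tryCatch(confint(object), error = function(e) NULL)
  tab <- cbind(estimate = object$estimates,
               se = object$se,
               lower = NA_real_, upper = NA_real_)
  if (!is.null(ci)) tab[object$free, c("lower", "upper")] <- ci
  structure(list(call = object$call, baseline = object$baseline,
                 table = tab, loglik = object$loglik, n = object$n,
                 level = object$level,
                 n_starts = object$n_starts_used,
                 n_starts_converged = object$n_starts_converged,
                 aic = 2 * length(object$free) - 2 * object$loglik),
            class = "summary.ltg_fit")
}

#' @export
print.summary.ltg_fit <- function(x, digits = 4, ...) {
  cat("Lomax-tangent ", x$baseline, " maximum-likelihood fit\n", sep = "")
  cat("n = ", x$n, ", log-likelihood = ", format(x$loglik, digits = digits + 2),
      ", AIC = ", format(x$aic, digits = digits + 2), "\n", sep = "")
  cat(100 * x$level, "% Wald intervals; ", x$n_starts_converged, "/",
      x$n_starts, " starts converged\n\n", sep = "")
  print(signif(x$table, digits))
  invisible(x)
}

#' @export
coef.ltg_fit <- function(object, ...) object$estimates

#' @export
vcov.ltg_fit <- function(object, ...) object$vcov

#' @export
logLik.ltg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free), nobs = object$n,
            class = "logLik")
}

#' Simulate from a fitted LT-G model
#'
#' @param object An `"ltg_fit"`.
#' @param nsim Number of replicate samples (each of the original size).
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of `n` draws each.
#' @export
simulate.ltg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(replicate(nsim, rltg(object$n, object$dist)))
}

#' Quantile residuals of an LT-G fit
#'
#' \eqn{r_i = \Phi^{-1}(F(x_i; \hat\Theta))}: standard normal under a
#' correctly specified model.
#'
#' @param object An `"ltg_fit"`.
#' @param ... Unused.
#' @return Numeric vector of quantile residuals.
#' @export
residuals.ltg_fit <- function(object, ...) {
  stats::qnorm(pmin(pmax(pltg(object$data, object$dist), 1e-15), 1 - 1e-15))
}

#' Serialize a fit to JSON
#'
#' @param fit An `"ltg_fit"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
ltg_fit_json <- function(fit, path = NULL) {
  obj <- list(baseline = fit$baseline,
              estimates = as.list(fit$estimates),
              se = as.list(fit$se),
              loglik = fit$loglik, n = fit$n,
              converged = fit$converged,
              n_starts_used = fit$n_starts_used)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
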