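#' Baseline distributions for the Lomax-tangent family
#'
#' A baseline is the parent distribution \eqn{G(x)} that the Lomax-tangent
#' generator is composed with.  Four baselines are shipped, matching the
#' family's named sub-models:
#'
#' \describe{
#'   \item{`"weibull"`}{\eqn{G(x) = 1 - e^{-(x/a)^b}} with shape `b` and
#'     scale `a` (sub-model LT-W).}
#'   \item{`"gamma"`}{\eqn{G(x) = \gamma(x, \beta)/\Gamma(\beta)}, the
#'     one-parameter (unit-scale) gamma with shape `beta` (LT-Ga).  An
#'     optional second element of `xi` is read as a scale parameter
#'     `theta`; this is an extension beyond the canonical one-parameter
#'     form and defaults to 1.}
#'   \item{`"rayleigh"`}{\eqn{G(x) = 1 - e^{-\beta x^2}} with rate-like
#'     parameter `beta` (LT-R).}
#'   \item{`"exponential"`}{\eqn{G(x) = 1 - e^{-\beta x}} with rate `beta`
#'     (LT-E).}
#' }
#'
#' Each baseline object carries the density `d`, distribution function `p`
#' (with `lower.tail` support, needed for numerically stable upper tails),
#' quantile function `q`, the derivative of the log-density `dlogg`
#' (used by the shape analysis), parameter names and the support.
#' Outside the support the cdf clamps to exact 0/1 rather than erroring,
#' so the composed family functions are total.
#'
#' @param name Baseline name; one of `ltg_baselines()`.
#' @return An object of class `"ltg_baseline"`: a list with elements
#'   `name`, `param_names`, `support`, and functions `d(x, xi, log)`,
#'   `p(q, xi, lower.tail)`, `q(p, xi, lower.tail)`, `dlogg(x, xi)`,
#'   `check(xi)`.
#' @examples
#' b <- ltg_baseline("weibull")
#' b$p(2, c(b = 3, a = 2))        # 1 - exp(-1)
#' b$q(0.5, c(b = 1, a = 1))      # log(2)
#' @seealso [ltg()] for composing a baseline into the full family.
#' @export
ltg_baseline <- function(name) {
  name <- match.arg(tolower(name), ltg_baselines())
  .ltg_baseline_registry[[name]]
}

#' List the available baseline names
#'
#' @return Character vector of registered baseline identifiers.
#' @export
ltg_baselines <- function() {
  c("weibull", "gamma", "rayleigh", "exponential")
}

# parameter validation shared by all baselines: every baseline parameter
# of the shipped models must be strictly positive
.check_positive <- function(xi, nms) {
  xi <- as.numeric(xi)
  labs <- if (length(xi) <= length(nms)) nms[seq_along(xi)] else
    c(nms, paste0("xi", seq.int(length(nms) + 1L, length(xi))))
  bad <- !is.finite(xi) | xi <= 0
  if (any(bad)) {
    stop("baseline parameter(s) must be strictly positive: ",
         paste(labs[bad], "=", xi[bad], collapse = ", "), call. = FALSE)
  }
  invisible(xi)
}

# clamp a cdf evaluation so values outside the support give exact 0/1
.clamp01 <- function(v) pmin(pmax(v, 0), 1)

.ltg_baseline_registry <- list(

  weibull = structure(list(
    name = "weibull",
    param_names = c("b", "a"),   # b shape, a scale
    support = c(0, Inf),
    check = function(xi) .check_positive(xi, c("b", "a")),
    d = function(x, xi, log = FALSE) {
      out <- stats::dweibull(pmax(x, 0), shape = xi[1], scale = xi[2], log = log)
      out[x <= 0] <- if (log) -Inf else 0
      out
    },
    p = function(q, xi, lower.tail = TRUE) {
      stats::pweibull(pmax(q, 0), shape = xi[1], scale = xi[2],
                      lower.tail = lower.tail)
    },
    q = function(p, xi, lower.tail = TRUE) {
      stats::qweibull(p, shape = xi[1], scale = xi[2], lower.tail = lower.tail)
    },
    dlogg = function(x, xi) {
      (xi[1] - 1) / x - (xi[1] / xi[2]) * (x / xi[2])^(xi[1] - 1)
    }
  ), class = "ltg_baseline"),

  gamma = structure(list(
    name = "gamma",
    param_names = c("beta"),
    support = c(0, Inf),
    check = function(xi) .check_positive(xi, c("beta", "theta")),
    d = function(x, xi, log = FALSE) {
      th <- if (length(xi) > 1) xi[2] else 1
      out <- stats::dgamma(pmax(x, 0), shape = xi[1], scale = th, log = log)
      out[x <= 0] <- if (log) -Inf else 0
      out
    },
    p = function(q, xi, lower.tail = TRUE) {
      th <- if (length(xi) > 1) xi[2] else 1
      stats::pgamma(pmax(q, 0), shape = xi[1], scale = th,
                    lower.tail = lower.tail)
    },
    q = function(p, xi, lower.tail = TRUE) {
      th <- if (length(xi) > 1) xi[2] else 1
      stats::qgamma(p, shape = xi[1], scale = th, lower.tail = lower.tail)
    },
    dlogg = function(x, xi) {
      th <- if (length(xi) > 1) xi[2] else 1
      (xi[1] - 1) / x - 1 / th
    }
  ), class = "ltg_baseline"),

  rayleigh = structure(list(
    name = "rayleigh",
    param_names = c("beta"),
    support = c(0, Inf),
    check = function(xi) .check_positive(xi, "beta"),
    d = function(x, xi, log = FALSE) {
      ld <- log(2 * xi[1]) + log(pmax(x, 0)) - xi[1] * x^2
      ld[x <= 0] <- -Inf
      if (log) ld else exp(ld)
    },
    p = function(q, xi, lower.tail = TRUE) {
      q <- pmax(q, 0)
      if (lower.tail) -expm1(-xi[1] * q^2) else exp(-xi[1] * q^2)
    },
    q = function(p, xi, lower.tail = TRUE) {
      if (lower.tail) sqrt(-log1p(-p) / xi[1]) else sqrt(-log(p) / xi[1])
    },
    dlogg = function(x, xi) 1 / x - 2 * xi[1] * x
  ), class = "ltg_baseline"),

  exponential = structure(list(
    name = "exponential",
    param_names = c("beta"),
    support = c(0, Inf),
    check = function(xi) .check_positive(xi, "beta"),
    d = function(x, xi, log = FALSE) {
      out <- stats::dexp(pmax(x, 0), rate = xi[1], log = log)
      out[x < 0] <- if (log) -Inf else 0
      out
    },
    p = function(q, xi, lower.tail = TRUE) {
      stats::pexp(pmax(q, 0), rate = xi[1], lower.tail = lower.tail)
    },
    q = function(p, xi, lower.tail = TRUE) {
      stats::qexp(p, rate = xi[1], lower.tail = lower.tail)
    },
    dlogg = function(x, xi) rep.int(-xi[1], length(x))
  ), class = "ltg_baseline")
)

#' @export
print.ltg_baseline <- function(x, ...) {
  cat("LT-G baseline: ", x$name, "\n",
      "  parameters: ", paste(x$param_names, collapse = ", "), "\n",
      "  support:    (", x$support[1], ", ", x$support[2], ")\n", sep = "")
  invisible(x)
}
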