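# exp-G series machinery: the family cdf admits the formal expansion
#   F(x) = sum_{i>=1} sum_{j>=0} W_{i,j} [G(x)]^(2j+i),
#   W_{i,j} = -C(-k, i) s^{-i} b_j^{(i)} (pi/2)^(2j+i),
# where b_j^{(i)} are the Maclaurin coefficients of tan(z)^i,
#   tan(z)^i = sum_j b_j^{(i)} z^(2j+i).
# The outer series converges where tan(pi*G/2)/s < 1, i.e.
# G < (2/pi) arctan(s); the closed forms remain the production path
# everywhere and the series is an analytic cross-check.

# ---- exact rational arithmetic (reduced numerator/denominator pairs) ----
# Small exact-fraction kernel used only for the tan-power coefficients,
# which the contract requires as exact rationals.  Numerators and
# denominators are stored in doubles; any intermediate that would leave
# the exactly-representable integer range raises a depth error rather
# than silently losing exactness.

.FRAC_MAX <- 2^53

.frac_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

.frac_check <- function(v) {
  if (abs(v) >= .FRAC_MAX)
    stop("series truncation depth limit exceeded: exact rational arithmetic ",
         "would overflow; reduce i/j or use the floating-point weights",
         call. = FALSE)
  v
}

.frac <- function(num, den = 1) {
  if (den < 0) { num <- -num; den <- -den }
  g <- .frac_gcd(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(.frac_check(num), .frac_check(den))
}

.frac_add <- function(x, y) {
  g <- .frac_gcd(x[2], y[2])
  d1 <- x[2] / g
  .frac(x[1] * (y[2] / g) + y[1] * d1, .frac_check(d1 * y[2]))
}

.frac_mul <- function(x, y) {
  g1 <- .frac_gcd(abs(x[1]), y[2])
  g2 <- .frac_gcd(abs(y[1]), x[2])
  .frac(.frac_check((x[1] / g1) * (y[1] / g2)),
        .frac_check((x[2] / g2) * (y[2] / g1)))
}

# Exact tangent Maclaurin coefficients t_1, t_3, ..., t_(2m-1) as reduced
# fractions: t_(2n-1) = T_n / (2n-1)! with T_n the tangent numbers from
# the Seidel (boustrophedon) triangle.
.tan_frac_coeffs <- function(m) {
  # tangent numbers T_n = a_(2n-1) (zigzag numbers) via the Entringer
  # recurrence E(n, k) = E(n, k-1) + E(n-1, n-k), a_n = E(n, n)
  N <- 2L * m - 1L
  Tn <- numeric(m)
  Eprev <- 1  # row n = 0
  Tn[1] <- 1
  for (n in 1:N) {
    Ecur <- numeric(n + 1L)
    for (k in 1:n)
      Ecur[k + 1L] <- .frac_check(Ecur[k] + Eprev[n - k + 1L])
    Eprev <- Ecur
    if (n %% 2 == 1) Tn[(n + 1L) / 2L] <- Ecur[n + 1L]
  }
  # reduce T_n / (2n-1)! progressively so the factorial never materializes
  out <- vector("list", m)
  for (n in 1:m) {
    num <- Tn[n]; den <- 1
    if (n > 1) for (f in 2:(2 * n - 1)) {
      den <- den * f
      g <- .frac_gcd(num, den)
      if (g > 1) { num <- num / g; den <- den / g }
      .frac_check(den)
    }
    out[[n]] <- .frac(num, den)
  }
  out
}

#' Exact coefficients of the tangent power series
#'
#' Returns \eqn{b_j^{(i)}}, the coefficient of \eqn{z^{2j+i}} in the
#' Maclaurin expansion of \eqn{\tan(z)^i}, computed by repeated formal
#' power-series multiplication in exact rational arithmetic.  The first
#' few obey \eqn{b_0^{(i)} = 1}, \eqn{b_1^{(i)} = i/3},
#' \eqn{b_2^{(i)} = i(5i+7)/90}.
#'
#' @param i Positive integer power of the tangent series.
#' @param j Nonnegative integer term index.
#' @param as_fraction If `TRUE`, return the reduced `c(numerator,
#'   denominator)` pair instead of the numeric value.
#' @return The coefficient as a double (exact: both numerator and
#'   denominator are exactly representable), or the fraction pair.
#'   Indices deep enough that exact arithmetic would overflow raise an
#'   error; the floating-point series path ([ltg_expg_weights()]) has no
#'   such limit.
#' @examples
#' ltg_tan_coeff(1, 1)                      # 1/3
#' ltg_tan_coeff(2, 2, as_fraction = TRUE)  # c(17, 45)
#' @export
ltg_tan_coeff <- function(i, j, as_fraction = FALSE) {
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || i < 1) stop("'i' must be a positive integer")
  if (is.na(j) || j < 0) stop("'j' must be a nonnegative integer")
  ord <- 2L * j + i                      # target power of z
  m <- j + 1L                            # tangent coefficients needed per factor
  tf <- .tan_frac_coeffs(m)
  # fractions of tan(z)^p at odd-offset powers; index q = term with power 2q+p
  cur <- tf                               # power 1: coefficient of z^(2q+1)
  if (i > 1) for (p in 2:i) {
    new <- vector("list", j + 1L)
    for (q in 0:j) {
      acc <- c(0, 1)
      for (r in 0:q) acc <- .frac_add(acc, .frac_mul(cur[[q - r + 1L]], tf[[r + 1L]]))
      new[[q + 1L]] <- acc
    }
    cur <- new
  }
  fr <- cur[[j + 1L]]
  if (as_fraction) fr else fr[1] / fr[2]
}

# ---- floating-point series path (no depth limit) ----

# coefficients of tan(z) up to z^M by series division sin/cos
.tan_coeffs_num <- function(M) {
  msq <- 0:M
  s <- ifelse(msq %% 2 == 1, (-1)^((msq - 1) / 2) / factorial(msq), 0)
  co <- ifelse(msq %% 2 == 0, (-1)^(msq / 2) / factorial(msq), 0)
  t <- numeric(M + 1)
  for (m in 0:M) {
    acc <- s[m + 1]
    if (m >= 1) for (kk in 0:(m - 1)) acc <- acc - t[kk + 1] * co[m - kk + 1]
    t[m + 1] <- acc
  }
  t
}

# matrix B[i, j+1] = b_j^(i) for i = 1..i_max, j = 0..j_max (doubles)
.tan_power_table <- function(i_max, j_max) {
  M <- 2L * j_max + i_max
  t1 <- .tan_coeffs_num(M)
  B <- matrix(0, i_max, j_max + 1L)
  cur <- t1
  for (i in 1:i_max) {
    if (i > 1) {
      new <- numeric(M + 1)
      for (m in 0:M) {
        acc <- 0
        for (kk in 0:m) acc <- acc + cur[kk + 1] * t1[m - kk + 1]
        new[m + 1] <- acc
      }
      cur <- new
    }
    for (j in 0:j_max) {
      p <- 2L * j + i
      if (p <= M) B[i, j + 1L] <- cur[p + 1L]
    }
  }
  B
}

#' exp-G mixture weights of the LT-G cdf expansion
#'
#' Term \eqn{(i, j)} of the formal expansion carries power
#' \eqn{2j + i} and weight
#' \eqn{W_{i,j} = -\binom{-k}{i} s^{-i} b_j^{(i)} (\pi/2)^{2j+i}}, with
#' the generalized binomial coefficient evaluated through
#' log-gamma so extreme `k` does not overflow (the weight is carried as
#' log-magnitude plus sign).
#'
#' @param k,s Generator shape and scale.
#' @param i_max,j_max Truncation bounds (both at least 1).
#' @return A data frame with columns `i`, `j`, `power` (\eqn{2j+i}),
#'   `weight`, `log_abs_weight` and `sign`.
#' @seealso [ltg_cdf_series()] for the truncated cdf built from these
#'   weights.
#' @export
ltg_expg_weights <- function(k, s, i_max = 20, j_max = 20) {
  if (i_max < 1 || j_max < 1) stop("truncation bounds must be >= 1")
  if (k <= 0 || s <= 0) stop("'k' and 's' must be strictly positive")
  B <- .tan_power_table(i_max, j_max)
  grid <- expand.grid(i = seq_len(i_max), j = 0:j_max)
  i <- grid$i; j <- grid$j
  b <- B[cbind(i, j + 1L)]
  # -C(-k, i) = (-1)^(i+1) C(k+i-1, i): log magnitude via lchoose
  lmag <- lchoose(k + i - 1, i) - i * log(s) + (2 * j + i) * log(pi / 2) + log(b)
  sgn <- (-1)^(i + 1)
  data.frame(i = i, j = j, power = 2 * j + i,
             weight = sgn * exp(lmag), log_abs_weight = lmag, sign = sgn)
}

#' Truncated series cdf of the LT-G family
#'
#' Evaluates the exp-G expansion of the cdf, truncated at `i_max`,
#' `j_max`.  The expansion converges where
#' \eqn{\tan(\pi G(x)/2) < s}, i.e. \eqn{G(x) < (2/\pi)\arctan(s)};
#' outside that region it diverges and the closed form [pltg()] must be
#' used.  Exposed as an analytic cross-check on the closed form.
#'
#' @param x Vector of quantiles.
#' @param d An `"ltg"` object.
#' @param i_max,j_max Truncation bounds.
#' @return Truncated cdf values.
#' @export
ltg_cdf_series <- function(x, d, i_max = 20, j_max = 20) {
  stopifnot(inherits(d, "ltg"))
  W <- ltg_expg_weights(d$k, d$s, i_max, j_max)
  G <- d$baseline$p(x, d$xi, lower.tail = TRUE)
  out <- numeric(length(x))
  pos <- G > 0
  if (any(pos)) {
    lg <- log(G[pos])
    # sum_t sign_t exp(log|W_t| + power_t * log G)
    out[pos] <- colSums(W$sign * exp(outer(W$log_abs_weight, rep(1, sum(pos))) +
                                       outer(W$power, lg)))
  }
  out
}

#' Density of an order statistic from an LT-G sample
#'
#' For a sample of size `n`, the `i`-th order statistic has density
#' \deqn{f_{i:n}(x) = \frac{n!}{(i-1)!(n-i)!}
#'   \sum_{p=0}^{n-i} (-1)^p \binom{n-i}{p} f(x) F(x)^{p+i-1},}
#' a finite binomial sum equal to
#' \eqn{K f(x) F(x)^{i-1} [1-F(x)]^{n-i}}.  The log-space product form is
#' the computational path (exact and stable for any `n`); the alternating
#' binomial sum is exposed for cross-checking via `method = "binomial"`.
#'
#' @param x Vector of quantiles.
#' @param d An `"ltg"` object.
#' @param n Sample size.
#' @param i Rank, `1 <= i <= n`.
#' @param method `"stable"` (default) or `"binomial"`.
#' @param log If `TRUE`, return the log-density (stable method only).
#' @return Densities of the `i`-th order statistic.
#' @export
dltg_order <- function(x, d, n, i, method = c("stable", "binomial"),
                       log = FALSE) {
  stopifnot(inherits(d, "ltg"))
  method <- match.arg(method)
  n <- as.integer(n); i <- as.integer(i)
  if (is.na(n) || n < 1) stop("'n' must be a positive integer")
  if (is.na(i) || i < 1 || i > n) stop("rank 'i' must lie in [1, n]")
  lK <- lfactorial(n) - lfactorial(i - 1) - lfactorial(n - i)
  if (method == "stable") {
    lf <- dltg(x, d, log = TRUE)
    lF <- pltg(x, d, log.p = TRUE)
    lS <- pltg(x, d, lower.tail = FALSE, log.p = TRUE)
    out <- lK + lf + (i - 1) * lF + (n - i) * lS
    # 0 * -Inf at the support edges: the density there is 0
    out[is.nan(out)] <- -Inf
    if (log) out else exp(out)
  } else {
    f <- dltg(x, d)
    Fx <- pltg(x, d)
    p <- 0:(n - i)
    acc <- numeric(length(x))
    for (pp in p) acc <- acc + (-1)^pp * choose(n - i, pp) * Fx^(pp + i - 1)
    exp(lK) * f * acc
  }
}
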