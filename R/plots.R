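#' Plot an LT-G distribution
#'
#' Functional curves of the density, hazard rate and cdf over the
#' central quantile range.
#'
#' @param x An `"ltg"` object.
#' @param which Subset of `c("density", "hazard", "cdf")`.
#' @param xlim Plot range; defaults to `qltg(c(0.001, 0.995), x)`.
#' @param n Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @return The grid data frame, invisibly.
#' @export
plot.ltg <- function(x, which = c("density", "hazard", "cdf"),
                     xlim = NULL, n = 400, ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (is.null(xlim)) xlim <- qltg(c(0.001, 0.995), x)
  xs <- seq(xlim[1], xlim[2], length.out = n)
  dat <- data.frame(x = xs, density = dltg(xs, x), hazard = hltg(xs, x),
                    cdf = pltg(xs, x))
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) {
    graphics::plot(xs, dat[[w]], type = "l", xlab = "x", ylab = w,
                   main = paste("LT-G", w), ...)
  }
  invisible(dat)
}

#' Diagnostic plots for an LT-G fit
#'
#' Four panels: histogram with the fitted density, empirical cdf with
#' the fitted cdf, the scaled TTT plot of the data, and a quantile
#' residual normal Q-Q plot.
#'
#' @param x An `"ltg_fit"` object.
#' @param which Subset of `1:4`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.ltg_fit <- function(x, which = 1:4, ...) {
  if (!isTRUE(x$converged)) stop("fit did not converge")
  dat <- x$data
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::hist(dat, freq = FALSE, breaks = "FD", col = "grey90",
                   main = "Fitted density", xlab = "x")
    xs <- seq(min(dat), max(dat), length.out = 400)
    graphics::lines(xs, dltg(xs, x$dist), lwd = 2)
  }
  if (2 %in% which) {
    graphics::plot(stats::ecdf(dat), main = "Fitted cdf", xlab = "x",
                   ylab = "F(x)")
    xs <- seq(min(dat), max(dat), length.out = 400)
    graphics::lines(xs, pltg(xs, x$dist), lwd = 2, col = 2)
  }
  if (3 %in% which) {
    tt <- ltg_ttt(dat)
    graphics::plot(tt$u, tt$ttt, type = "b", pch = 20, cex = 0.5,
                   main = "TTT plot", xlab = "i/n", ylab = "T(i)/T(n)")
    graphics::abline(0, 1, lty = 2)
  }
  if (4 %in% which) {
    stats::qqnorm(residuals(x), main = "Quantile residuals")
    stats::qqline(residuals(x))
  }
  invisible(x)
}
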