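# Packaged benchmark data sets, stored as code so the package ships as
# plain text.  Both are reproduced verbatim from the primary literature
# on these classic benchmarks, in printed order.

# 72 exceedances (m^3/s) of flood peaks of the Wheaton River near
# Carcross, Yukon Territory, Canada (Choulakian & Stephens' classic
# right-skewed benchmark).
.wheaton <- c(
  1.7, 2.2, 14.4, 1.1, 0.4, 20.6, 5.3, 0.7, 1.9, 13.0, 12.0, 9.3,
  1.4, 18.7, 8.5, 25.5, 11.6, 14.1, 22.1, 1.1, 2.5, 14.4, 1.7, 37.6,
  0.6, 2.2, 39.0, 0.3, 15.0, 11.0, 7.3, 22.9, 1.7, 0.1, 1.1, 0.6,
  9.0, 1.7, 7.0, 20.1, 0.4, 2.8, 14.1, 9.9, 10.4, 10.7, 30.0, 3.6,
  5.6, 30.8, 13.3, 4.2, 25.5, 3.4, 11.9, 21.5, 27.6, 36.4, 2.7, 64.0,
  1.5, 2.5, 27.4, 1.0, 27.1, 20.2, 16.8, 5.3, 9.7, 27.5, 2.5, 27.0)

# 63 breaking strengths of 1.5 cm glass fibres (Smith & Naylor).
.glass_fibre <- c(
  0.55, 0.93, 1.25, 1.36, 1.49, 1.52, 1.58, 1.61, 1.64, 1.68, 1.73,
  1.81, 2.00, 0.74, 1.04, 1.27, 1.39, 1.49, 1.53, 1.59, 1.61, 1.66,
  1.68, 1.76, 1.82, 2.01, 0.77, 1.11, 1.28, 1.42, 1.50, 1.54, 1.60,
  1.62, 1.66, 1.69, 1.76, 1.84, 2.24, 0.81, 1.13, 1.29, 1.48, 1.50,
  1.55, 1.61, 1.62, 1.66, 1.70, 1.77, 1.84, 0.84, 1.24, 1.30, 1.48,
  1.51, 1.55, 1.61, 1.63, 1.67, 1.70, 1.78, 1.89)

.ltg_dataset_sources <- c(
  wheaton = "Choulakian & Stephens: flood-peak exceedances of the Wheaton River, Yukon (n = 72)",
  glass_fibre = "Smith & Naylor: strengths of 1.5 cm glass fibres (n = 63)")

#' Packaged benchmark data sets
#'
#' Two classic positive lifetime-type benchmarks: `"wheaton"`, the 72
#' flood-peak exceedances of the Wheaton River (strongly right-skewed),
#' and `"glass_fibre"`, the 63 breaking strengths of 1.5 cm glass
#' fibres (left-skewed, increasing hazard).
#'
#' @param name `"wheaton"` or `"glass_fibre"`.
#' @return Numeric vector with attributes `name` and `source`.
#' @examples
#' length(ltg_data("wheaton"))   # 72
#' max(ltg_data("glass_fibre"))  # 2.24
#' @export
ltg_data <- function(name) {
  name <- tolower(name)
  if (!name %in% names(.ltg_dataset_sources))
    stop("unknown data set '", name, "'; available: ",
         paste(names(.ltg_dataset_sources), collapse = ", "))
  v <- switch(name, wheaton = .wheaton, glass_fibre = .glass_fibre)
  attr(v, "name") <- name
  attr(v, "source") <- unname(.ltg_dataset_sources[name])
  v
}

#' List the packaged data sets
#'
#' @return Named character vector of data set sources.
#' @export
ltg_datasets <- function() .ltg_dataset_sources

#' Summary statistics of a sample
#'
#' Sample size, mean, standard deviation, and the moment-based (biased,
#' divide-by-n) sample skewness and kurtosis.  Kurtosis is reported in
#' both conventions, non-excess \eqn{b_2} and excess \eqn{b_2 - 3},
#' since published summaries use either without saying which.
#'
#' @param x Numeric data vector.
#' @return Object of class `"ltg_describe"`: list with `n`, `mean`,
#'   `sd`, `skewness`, `kurtosis`, `excess_kurtosis`, `min`, `max`.
#'   For constant input the shape measures are `NA` with a warning; for
#'   `n < 4` the kurtosis is `NA`.
#' @examples
#' ltg_describe(ltg_data("wheaton"))
#' @export
ltg_describe <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sk <- ku <- NA_real_
  if (m2 == 0) {
    warning("constant data: skewness and kurtosis undefined")
  } else {
    if (n >= 3) sk <- mean((x - m)^3) / m2^1.5
    if (n >= 4) ku <- mean((x - m)^4) / m2^2
  }
  structure(list(n = n, mean = m, sd = stats::sd(x), skewness = sk,
                 kurtosis = ku, excess_kurtosis = ku - 3,
                 min = min(x), max = max(x)),
            class = "ltg_describe")
}

#' @export
print.ltg_describe <- function(x, digits = 4, ...) {
  cat("n = ", x$n, ", range [", x$min, ", ", x$max, "]\n", sep = "")
  cat("mean ", signif(x$mean, digits), ", sd ", signif(x$sd, digits),
      "\n", sep = "")
  cat("skewness ", signif(x$skewness, digits),
      ", kurtosis ", signif(x$kurtosis, digits),
      " (excess ", signif(x$excess_kurtosis, digits), ")\n", sep = "")
  invisible(x)
}
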