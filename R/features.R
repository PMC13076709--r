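# Eleven first-order radiomic features of an ADC sample.

FEATURE_NAMES <- c("mean", "sd", "median", "iqr", "p10", "p25", "p75", "p90",
                   "kurtosis", "skewness", "entropy")

#' Compute the eleven first-order radiomic features of an ADC sample
#'
#' Moments and percentiles are computed from the raw voxel values: sample
#' standard deviation (n - 1), type-7 linearly interpolated percentiles,
#' skewness `m3 / m2^(3/2)` and non-excess kurtosis `m4 / m2^2` (central
#' moments with 1/n, so a normal population gives kurtosis near 3). Entropy
#' is computed from the fixed-bin histogram on `spec`:
#' `-sum(p_k * log2(p_k))` over non-empty bins, in bits. A constant sample
#' leaves skewness and kurtosis undefined (`NA`), not an error.
#'
#' @param sample an `adc_sample` or numeric vector (length >= 1; >= 2 for a
#'   defined sd).
#' @param spec optional `hist_spec` for the entropy binning; if omitted, a
#'   spec is built from the sample alone.
#' @return Named numeric vector of length 11 (class `feature_vector`).
#' @export
compute_features <- function(sample, spec = NULL) {
  vals <- if (inherits(sample, "adc_sample")) sample$values else sample
  vals <- vals[is.finite(vals)]
  n <- length(vals)
  if (!n) stopf("empty sample")
  spec <- spec %||% build_shared_spec(list(vals))

  q <- stats::quantile(vals, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = 7, names = FALSE)
  m <- mean(vals)
  s <- if (n >= 2) stats::sd(vals) else NA_real_
  m2 <- mean((vals - m)^2)
  if (m2 > 0) {
    skew <- mean((vals - m)^3) / m2^1.5
    kurt <- mean((vals - m)^4) / m2^2
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  p <- compute_histogram(vals, spec)$counts
  p <- p[p > 0] / sum(p)
  entropy <- -sum(p * log2(p))

  structure(c(mean = m, sd = s, median = q[3], iqr = q[4] - q[2],
              p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
              kurtosis = kurt, skewness = skew, entropy = entropy),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}
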