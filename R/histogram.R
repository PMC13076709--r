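# Fixed-bin ADC histograms on a shared bin vector.
#
# All histograms that will be compared (across reconstruction levels and
# repeats of one VOI) share a single bin grid with a fixed 5e-6 mm^2/s bin
# width spanning the pooled min/max, so bin counts are directly comparable.

#' Build a shared histogram specification from a pool of samples
#'
#' The range is the global min/max over all supplied samples, aligned
#' outward to multiples of `bin_width`. A degenerate (single-point) pool
#' yields a single bin containing it.
#'
#' @param samples list of `adc_sample`s (or bare numeric vectors).
#' @param bin_width bin width in mm^2/s (default 5e-6).
#' @return A `hist_spec`: list with `bin_width`, `x_min`, `x_max`,
#'   `n_bins`, `edges`.
#' @export
build_shared_spec <- function(samples, bin_width = 5e-6) {
  if (inherits(samples, "adc_sample") || is.numeric(samples))
    samples <- list(samples)
  vals <- unlist(lapply(samples, function(s)
    if (inherits(s, "adc_sample")) s$values else s), use.names = FALSE)
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("cannot build a histogram spec from empty samples")
  if (bin_width <= 0) stopf("bin_width must be positive")
  # align outward; tiny fuzz keeps values that are exact multiples of the
  # width from widening the grid through floating-point slop
  eps <- 1e-9
  kmin <- floor(min(vals) / bin_width + eps)
  kmax <- ceiling(max(vals) / bin_width - eps)
  if (kmax <= kmin) kmax <- kmin + 1
  n_bins <- as.integer(kmax - kmin)
  structure(list(bin_width = bin_width,
                 x_min = kmin * bin_width, x_max = kmax * bin_width,
                 n_bins = n_bins,
                 edges = (kmin + 0:n_bins) * bin_width),
            class = "hist_spec")
}

specs_identical <- function(a, b) {
  isTRUE(all.equal(a$edges, b$edges, tolerance = 1e-12)) &&
    a$n_bins == b$n_bins
}

#' Compute a fixed-bin histogram of an ADC sample
#'
#' Bins are half-open `[edge_k, edge_{k+1})` with the last bin closed;
#' values exactly on an interior edge fall in the upper bin.
#'
#' @param sample an `adc_sample` or numeric vector; all values must lie in
#'   the spec range.
#' @param spec a `hist_spec`.
#' @return An `adc_histogram`: list with `spec`, `counts`, `provenance`.
#' @export
compute_histogram <- function(sample, spec) {
  stopifnot(inherits(spec, "hist_spec"))
  vals <- if (inherits(sample, "adc_sample")) sample$values else sample
  prov <- if (inherits(sample, "adc_sample")) sample$provenance else NULL
  if (!length(vals)) stopf("empty sample")
  if (any(vals < spec$x_min) || any(vals > spec$x_max))
    stopf("sample values outside histogram spec range; build the spec from the same pool")
  idx <- findInterval(vals, spec$edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = spec$n_bins)
  structure(list(spec = spec, counts = as.numeric(counts), provenance = prov),
            class = "adc_histogram")
}

#' Average histograms bin-by-bin
#'
#' The mean histogram over repeated measurements; all inputs must share one
#' spec. Counts become reals.
#'
#' @param histograms list of `adc_histogram`s on an identical spec.
#' @return An `adc_histogram` with the per-bin arithmetic mean counts.
#' @export
mean_histogram <- function(histograms) {
  if (!length(histograms)) stopf("no histograms to average")
  h1 <- histograms[[1]]
  for (h in histograms[-1]) {
    if (!specs_identical(h$spec, h1$spec))
      stopf("histograms do not share a spec")
  }
  counts <- Reduce(`+`, lapply(histograms, `[[`, "counts")) / length(histograms)
  structure(list(spec = h1$spec, counts = counts, provenance = h1$provenance),
            class = "adc_histogram")
}
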