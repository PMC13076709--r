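# Mono-exponential ADC fitting: ordinary least squares of log-signal
# against b-value, voxelwise.

#' Fit the mono-exponential decay model to one signal series
#'
#' Unweighted OLS of `ln(S)` on `b` over the b-values with strictly positive
#' signal; `adc = -slope`, `s0 = exp(intercept)`. Fewer than two positive
#' signals leaves the fit undefined; a negative fitted ADC is clamped to 0
#' and flagged.
#'
#' @param signals numeric vector of magnitudes, one per b-value.
#' @param b_values numeric vector of b-values (s/mm^2).
#' @return List with `adc` (mm^2/s or `NA`), `s0`, `n_points_used`,
#'   `clamped` (logical).
#' @export
fit_adc_signal <- function(signals, b_values) {
  if (length(signals) != length(b_values))
    stopf("signals and b_values must have equal length")
  if (length(b_values) < 2) stopf("need at least two b-values")
  pos <- is.finite(signals) & signals > 0
  n <- sum(pos)
  if (n < 2)
    return(list(adc = NA_real_, s0 = NA_real_, n_points_used = n, clamped = FALSE))
  b <- b_values[pos]
  y <- log(signals[pos])
  bm <- mean(b)
  ym <- mean(y)
  slope <- sum((b - bm) * (y - ym)) / sum((b - bm)^2)
  adc <- -slope
  clamped <- adc < 0
  if (clamped) adc <- 0
  list(adc = adc, s0 = exp(ym - slope * bm), n_points_used = n, clamped = clamped)
}

#' Fit an ADC map voxelwise from a DWI stack
#'
#' Vectorized equivalent of applying [fit_adc_signal()] to every voxel.
#' Voxels whose b = 0 signal falls below `signal_floor` (default
#' `signal_floor_sigma * noise_sigma` from the protocol) are marked missing,
#' as are voxels with fewer than two positive signals.
#'
#' @param stack a `dwi_stack`.
#' @param signal_floor optional numeric floor on the b = 0 signal.
#' @return An `adc_map`: list with `values` (3D array, mm^2/s, `NA` where
#'   undefined), `pixel_mm`, `slice_mm`, `provenance`, `n_clamped`.
#' @export
fit_adc_map <- function(stack, signal_floor = NULL) {
  stopifnot(inherits(stack, "dwi_stack"))
  p <- stack$protocol
  b <- p$b_values
  nb <- length(b)
  dm <- dim(stack$data)
  nvox <- prod(dm[1:3])
  S <- matrix(stack$data, nvox, nb)

  pos <- S > 0
  L <- matrix(0, nvox, nb)
  L[pos] <- log(S[pos])
  W <- pos + 0
  n <- rowSums(W)
  Sb <- as.vector(W %*% b)
  Sb2 <- as.vector(W %*% (b^2))
  Sy <- rowSums(L)
  Sby <- as.vector(L %*% b)
  den <- n * Sb2 - Sb^2

  adc <- rep(NA_real_, nvox)
  ok <- n >= 2 & den > 0
  adc[ok] <- -(n[ok] * Sby[ok] - Sb[ok] * Sy[ok]) / den[ok]
  clamp <- ok & adc < 0
  adc[clamp] <- 0

  floor_val <- signal_floor %||% (p$signal_floor_sigma * p$noise_sigma)
  if (floor_val > 0) adc[S[, 1] < floor_val] <- NA_real_

  structure(list(values = array(adc, dim = dm[1:3]),
                 pixel_mm = p$pixel_mm, slice_mm = p$slice_mm,
                 provenance = list(sequence = p$sequence, level = stack$level,
                                   session = stack$session_id,
                                   repeat_id = stack$repeat_id),
                 n_clamped = sum(clamp)),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<adc_map> %dx%dx%d, %d defined voxels, level=%s\n",
              d[1], d[2], d[3], sum(is.finite(x$values)),
              x$provenance$level %||% "?"))
  invisible(x)
}
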