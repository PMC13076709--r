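# Distributional comparisons across reconstruction levels.

#' Wasserstein distance between two same-spec histograms
#'
#' Both histograms are normalized to relative frequencies, cumulated over
#' bins, and the distance is the sum of absolute differences between the
#' two cumulative curves — in bin-index units (no bin-width scaling), so a
#' unit mass translated by k bins is at distance exactly k.
#'
#' @param h1,h2 `adc_histogram`s on an identical spec.
#' @return Non-negative scalar.
#' @export
wasserstein_distance <- function(h1, h2) {
  stopifnot(inherits(h1, "adc_histogram"), inherits(h2, "adc_histogram"))
  if (!specs_identical(h1$spec, h2$spec))
    stopf("histograms do not share a spec")
  s1 <- sum(h1$counts)
  s2 <- sum(h2$counts)
  if (s1 <= 0 || s2 <= 0) stopf("zero-mass histogram")
  sum(abs(cumsum(h1$counts / s1) - cumsum(h2$counts / s2)))
}

#' Friedman test across reconstruction levels, paired by voxel
#'
#' Blocks are voxels, treatments are the levels. Within-block mid-ranks,
#' tie-corrected chi-square statistic with k - 1 degrees of freedom, upper
#' tail p-value. If every block is fully tied the test is degenerate and
#' `p = 1` is returned with a flag.
#'
#' @param samples list of k >= 2 equal-length numeric vectors (or
#'   `adc_sample`s), one per level, paired elementwise.
#' @return List with `statistic`, `df`, `p`, `degenerate`.
#' @export
friedman_across_levels <- function(samples) {
  vals <- lapply(samples, function(s)
    if (inherits(s, "adc_sample")) s$values else s)
  k <- length(vals)
  if (k < 2) stopf("need at least two levels")
  n <- unique(vapply(vals, length, 1L))
  if (length(n) != 1) stopf("samples must have equal length (paired by voxel)")
  if (n < 2) stopf("need at least two blocks")
  X <- do.call(cbind, vals)
  R <- t(apply(X, 1, rank))
  Rj <- colSums(R)
  # tie correction: sum of (t^3 - t) over tie groups within each block
  tie_sum <- sum(apply(X, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C <= 0) {
    return(list(statistic = NA_real_, df = k - 1L, p = 1, degenerate = TRUE))
  }
  stat <- (12 * sum((Rj - n * (k + 1) / 2)^2) / (n * k * (k + 1))) / C
  list(statistic = stat, df = k - 1L,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# Exact null distribution of the doubled signed-rank sum via dynamic
# programming over all 2^n sign assignments (ranks doubled so mid-ranks
# become integers). Returns probability vector over 0..sum(dr).
signed_rank_null <- function(dr) {
  total <- sum(dr)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in dr) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  f / 2^length(dr)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences get mid-ranks.
#' For n <= `exact_max` pairs the exact null distribution of the rank sum
#' (conditional on the observed tie pattern) is used; beyond that, a normal
#' approximation with continuity and tie correction.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is computed
#'   (default 25).
#' @return List with `p`, `statistic` (rank sum of positive differences),
#'   `n` (pairs after dropping zeros), `degenerate`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(p = 1, statistic = NA_real_, n = 0L, degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    dr <- as.integer(round(2 * r))
    null <- signed_rank_null(dr)
    w2 <- as.integer(round(2 * W))
    lower <- sum(null[seq_len(w2 + 1)])
    upper <- sum(null[(w2 + 1):length(null)])
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = p, statistic = W, n = n, degenerate = FALSE)
}

#' Percent difference of a feature relative to baseline
#'
#' `100 * (feature_dl - feature_off) / feature_off`, vectorized; a zero (or
#' undefined) baseline yields `NA`.
#'
#' @param feature_off baseline (denoising OFF) feature value(s).
#' @param feature_dl feature value(s) under a denoising level.
#' @return Percent difference(s).
#' @export
percent_difference <- function(feature_off, feature_dl) {
  out <- 100 * (feature_dl - feature_off) / feature_off
  out[!is.finite(feature_off) | feature_off == 0] <- NA_real_
  out
}
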