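# Independent oracle implementations used to validate package operations.
# These deliberately avoid the code paths they check.

# Closed-form OLS on (b, log S) via the normal equations through stats::lm.
oracle_ols_adc <- function(signals, b_values) {
  keep <- signals > 0
  fit <- stats::lm(log(signals[keep]) ~ b_values[keep])
  list(adc = -unname(stats::coef(fit)[2]), s0 = exp(unname(stats::coef(fit)[1])))
}

# Brute-force per-value bin assignment (half-open bins, last closed).
oracle_histogram <- function(values, edges) {
  nb <- length(edges) - 1
  vapply(seq_len(nb), function(k) {
    if (k < nb) sum(values >= edges[k] & values < edges[k + 1])
    else sum(values >= edges[k] & values <= edges[k + 1])
  }, numeric(1))
}

# Textbook first-order features, written independently (manual type-7
# percentile interpolation, explicit moment sums, direct entropy).
oracle_features <- function(v, edges) {
  n <- length(v)
  sv <- sort(v)
  pct <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h) + 1
    sv[lo] + (h - floor(h)) * (sv[min(lo + 1, n)] - sv[lo])
  }
  m <- sum(v) / n
  m2 <- sum((v - m)^2) / n
  m3 <- sum((v - m)^3) / n
  m4 <- sum((v - m)^4) / n
  counts <- oracle_histogram(v, edges)
  p <- counts[counts > 0] / sum(counts)
  c(mean = m, sd = sqrt(sum((v - m)^2) / (n - 1)), median = pct(0.5),
    iqr = pct(0.75) - pct(0.25), p10 = pct(0.1), p25 = pct(0.25),
    p75 = pct(0.75), p90 = pct(0.9), kurtosis = m4 / m2^2,
    skewness = m3 / m2^1.5, entropy = -sum(p * log2(p)))
}

# Wasserstein distance by explicit loop over bins.
oracle_wasserstein <- function(c1, c2) {
  f1 <- c1 / sum(c1)
  f2 <- c2 / sum(c2)
  tot <- 0
  a <- 0
  b <- 0
  for (k in seq_along(f1)) {
    a <- a + f1[k]
    b <- b + f2[k]
    tot <- tot + abs(a - b)
  }
  tot
}

# Exhaustive 2^n sign enumeration for the two-sided signed-rank p-value.
oracle_wilcoxon_exact <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}
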