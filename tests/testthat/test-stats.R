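make_hist <- function(counts, spec) {
  structure(list(spec = spec, counts = as.numeric(counts), provenance = NULL),
            class = "adc_histogram")
}

test_that("wasserstein_distance: identity, shifts, and small closed forms", {
  spec3 <- build_shared_spec(list(c(0, 3e-3)), bin_width = 1e-3)
  ha <- make_hist(c(1, 0, 0), spec3)
  hb <- make_hist(c(0, 0, 1), spec3)
  expect_equal(wasserstein_distance(ha, ha), 0)
  expect_equal(wasserstein_distance(ha, hb), 2)
  hc <- make_hist(c(0.5, 0.5, 0), spec3)
  hd <- make_hist(c(0, 0.5, 0.5), spec3)
  expect_equal(wasserstein_distance(hc, hd), 1)

  expect_error(wasserstein_distance(ha, make_hist(c(0, 0, 0), spec3)), "zero-mass")
  other <- build_shared_spec(list(c(0, 4e-3)), bin_width = 1e-3)
  expect_error(wasserstein_distance(ha, make_hist(c(1, 1, 1, 1), other)),
               "share a spec")
})

test_that("wasserstein_distance matches brute force; metric properties hold", {
  set.seed(606)
  spec <- build_shared_spec(list(c(0, 20e-3)), bin_width = 1e-3)
  for (i in 1:40) {
    c1 <- rpois(20, 5)
    c2 <- rpois(20, 5)
    c1[1] <- c1[1] + 1  # guarantee mass
    c2[1] <- c2[1] + 1
    h1 <- make_hist(c1, spec)
    h2 <- make_hist(c2, spec)
    d <- wasserstein_distance(h1, h2)
    expect_equal(d, oracle_wasserstein(c1, c2), tolerance = 1e-12)
    expect_equal(d, wasserstein_distance(h2, h1))
    c3 <- rpois(20, 5)
    c3[1] <- c3[1] + 1
    h3 <- make_hist(c3, spec)
    expect_lte(d, wasserstein_distance(h1, h3) + wasserstein_distance(h3, h2) + 1e-10)
  }
  # pure translation of a unit mass: distance equals the shift in bins
  for (k in c(1, 4, 9)) {
    a <- numeric(20); a[3] <- 2
    b <- numeric(20); b[3 + k] <- 2
    expect_equal(wasserstein_distance(make_hist(a, spec), make_hist(b, spec)), k)
  }
})

test_that("friedman_across_levels: hand-computed example and degeneracy", {
  # ranks by hand: blocks (1,2,3,4),(2,1,4,3),(1,2,3,4),(4,3,2,1)
  # column rank sums (8,8,12,12); n=4, k=4:
  # chi2 = 12/(4*4*5) * sum((Rj - 10)^2) = 0.15 * 16 = 2.4, no ties
  X <- rbind(c(10, 20, 30, 40),
             c(12, 11, 30, 25),
             c(5, 6, 7, 8),
             c(40, 30, 20, 10))
  fr <- friedman_across_levels(asplit(X, 2))
  expect_equal(fr$statistic, 2.4, tolerance = 1e-12)
  expect_equal(fr$p, pchisq(2.4, df = 3, lower.tail = FALSE))
  expect_false(fr$degenerate)

  all_tied <- friedman_across_levels(list(1:5, 1:5, 1:5, 1:5))
  expect_equal(all_tied$p, 1)
  expect_true(all_tied$degenerate)

  expect_error(friedman_across_levels(list(1:4, 1:5)), "equal length")
})

test_that("friedman matches stats::friedman.test on untied data", {
  set.seed(607)
  for (i in 1:10) {
    X <- matrix(rnorm(4 * 15), 15, 4)
    fr <- friedman_across_levels(asplit(X, 2))
    ref <- stats::friedman.test(X)
    expect_equal(fr$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(fr$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon_paired: closed forms, enumeration oracle, base-R agreement", {
  # six strictly positive differences: extreme rank sum, p = 2/2^6
  w <- wilcoxon_paired(rep(0, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(w$p, 2 / 64)
  expect_equal(w$statistic, 21)

  degen <- wilcoxon_paired(1:5, 1:5)
  expect_equal(degen$p, 1)
  expect_true(degen$degenerate)

  set.seed(608)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, 0.3)
    expect_equal(wilcoxon_paired(x, y)$p, oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12)
  }
  # agreement with stats::wilcox.test exact path (untied data)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- x + rnorm(15, 0.2)
    expect_equal(wilcoxon_paired(x, y)$p,
                 stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(609)
  x <- rnorm(20)
  y <- x + rnorm(20, 0.4)
  tr <- function(v) exp(v) + v^3
  # wilcoxon invariance needs a difference-sign-preserving transform:
  # monotone transforms preserve signs and |difference| order only for
  # ranks within pairs, so compare through friedman on 4 columns instead
  X <- cbind(x, y, x + rnorm(20, 0.1), y + rnorm(20, 0.1))
  f1 <- friedman_across_levels(asplit(X, 2))
  f2 <- friedman_across_levels(asplit(tr(X), 2))
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("percent_difference handles signs, zero baselines, and vectors", {
  expect_equal(percent_difference(2, 1), -50)
  expect_equal(percent_difference(3, 3), 0)
  expect_true(is.na(percent_difference(0, 1)))
  v <- percent_difference(c(2, 4), c(3, 3))
  expect_equal(v, c(50, -25))
  # aggregation equals direct formulas
  set.seed(610)
  off <- runif(13, 1, 2)
  dl <- off * runif(13, 0.8, 1.2)
  pd <- percent_difference(off, dl)
  expect_equal(mean(pd), mean(100 * (dl - off) / off), tolerance = 1e-12)
  expect_equal(sd(pd), sd(100 * (dl - off) / off), tolerance = 1e-12)
})
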