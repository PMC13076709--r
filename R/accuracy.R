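# Accuracy against nominal references and intra-session repeatability.

#' Signed percent deviation of a measurement from its nominal value
#'
#' @param measured measured value(s), same units as `nominal`.
#' @param nominal nominal reference, must be positive.
#' @return `100 * (measured - nominal) / nominal`.
#' @export
percent_deviation <- function(measured, nominal) {
  if (any(nominal <= 0)) stopf("nominal must be positive")
  100 * (measured - nominal) / nominal
}

#' Coefficient of variation of repeat measurements
#'
#' `100 * sd / mean` with the n - 1 standard deviation.
#'
#' @param values numeric vector of repeat measurements (length >= 2,
#'   positive mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stopf("need at least two repeats")
  m <- mean(values)
  if (m <= 0) stopf("mean must be positive")
  100 * stats::sd(values) / m
}

#' Extreme percent deviations from the first repeat
#'
#' Deviations of repeats 2..n from the first measurement; returns the
#' signed extrema `(min, max)` over those deviations (either may be
#' positive or negative if all deviations share a sign).
#'
#' @param values repeat measurements in acquisition order (length >= 2,
#'   first value positive).
#' @return Named numeric `c(neg = ..., pos = ...)` = (min, max) deviation %.
#' @export
max_percent_deviation <- function(values) {
  if (length(values) < 2) stopf("need at least two repeats")
  if (values[1] <= 0) stopf("first repeat must be positive")
  d <- 100 * (values[-1] - values[1]) / values[1]
  c(neg = min(d), pos = max(d))
}

#' Aggregate session-level results into pooled summaries
#'
#' Metric-specific pooling across the (two) sessions of a study result set:
#' CVs and Wasserstein distances are averaged per cell; maximum deviations
#' keep the signed extrema over sessions; accuracy deviations pool the
#' per-repeat values of both sessions and summarize them as median and IQR
#' per vial and level; feature percent differences pool per-vial,
#' per-session values and summarize as mean and n-1 SD per feature and
#' level pair.
#'
#' @param results a `study_result_set` from [run_study()] (or a compatible
#'   list of data.frames).
#' @return List of data.frames: `accuracy_pooled`, `cv_pooled`,
#'   `maxdev_pooled`, `wasserstein_pooled`, `percent_diff_pooled`.
#' @export
aggregate_sessions <- function(results) {
  need <- c("per_repeat", "repeatability", "comparisons", "feature_diffs")
  miss <- setdiff(need, names(results))
  if (length(miss)) stopf("results missing components: %s",
                          paste(miss, collapse = ", "))
  if (length(unique(results$per_repeat$session)) < 2)
    stopf("both sessions must be present for pooling")

  pr <- results$per_repeat
  acc <- do.call(rbind, lapply(
    split(pr, list(pr$sequence, pr$vial, pr$level), drop = TRUE),
    function(g) data.frame(
      sequence = g$sequence[1], vial = g$vial[1], level = g$level[1],
      n = nrow(g),
      median_dev = stats::median(g$deviation_percent),
      iqr_dev = stats::IQR(g$deviation_percent, type = 7))))

  rp <- results$repeatability
  cv <- do.call(rbind, lapply(
    split(rp, list(rp$sequence, rp$vial, rp$level), drop = TRUE),
    function(g) data.frame(
      sequence = g$sequence[1], vial = g$vial[1], level = g$level[1],
      cv_percent = mean(g$cv_percent))))
  md <- do.call(rbind, lapply(
    split(rp, list(rp$sequence, rp$vial, rp$level), drop = TRUE),
    function(g) data.frame(
      sequence = g$sequence[1], vial = g$vial[1], level = g$level[1],
      max_dev_neg = min(g$max_dev_neg), max_dev_pos = max(g$max_dev_pos))))

  cp <- results$comparisons
  ws <- do.call(rbind, lapply(
    split(cp, list(cp$sequence, cp$vial, cp$level), drop = TRUE),
    function(g) data.frame(
      sequence = g$sequence[1], vial = g$vial[1], level = g$level[1],
      wasserstein = mean(g$wasserstein))))

  fd <- results$feature_diffs
  pd <- do.call(rbind, lapply(
    split(fd, list(fd$sequence, fd$feature, fd$level), drop = TRUE),
    function(g) data.frame(
      sequence = g$sequence[1], feature = g$feature[1], level = g$level[1],
      n = sum(is.finite(g$percent_difference)),
      mean_percent_diff = mean(g$percent_difference, na.rm = TRUE),
      sd_percent_diff = stats::sd(g$percent_difference, na.rm = TRUE))))

  lapply(list(accuracy_pooled = acc, cv_pooled = cv, maxdev_pooled = md,
              wasserstein_pooled = ws, percent_diff_pooled = pd),
         function(d) { rownames(d) <- NULL; d })
}
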