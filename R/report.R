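# Human-readable reporting: per-feature trend tables across levels and a
# significance matrix of the paired Wilcoxon tests.

#' Render summary report files from a study result set
#'
#' Writes `trends.csv` (mean feature value across vials, per sequence,
#' session and level), `significance_matrix.csv` (feature x level-pair x
#' session Wilcoxon p-values, wide by level), and a plain-text
#' `summary.txt`. If no feature tests are present the significance matrix
#' is omitted with a notice.
#'
#' @param results a `study_result_set`.
#' @param out_dir directory to write into (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(results, out_dir) {
  if (is.null(results$features) || !nrow(results$features))
    stopf("empty result set")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  trends <- stats::aggregate(value ~ sequence + session + level + feature,
                             data = results$features, FUN = mean)
  trends <- trends[order(trends$sequence, trends$session, trends$feature), ]
  utils::write.csv(trends, file.path(out_dir, "trends.csv"), row.names = FALSE)

  lines <- c("adcphantom study summary", "")
  acc <- results$accuracy
  lines <- c(lines, sprintf(
    "Accuracy: deviations %.1f%% to %.1f%% over %d vial x level x session cells",
    min(acc$deviation_percent), max(acc$deviation_percent), nrow(acc)))
  rp <- results$repeatability
  lines <- c(lines, sprintf(
    "Repeatability: CV %.2f%% to %.2f%%; max deviations %.2f%% to %.2f%%",
    min(rp$cv_percent), max(rp$cv_percent),
    min(rp$max_dev_neg), max(rp$max_dev_pos)))
  cp <- results$comparisons
  hi <- cp[cp$level == "HIGH", ]
  if (nrow(hi)) {
    top <- hi[which.max(hi$wasserstein), ]
    lines <- c(lines, sprintf(
      "Wasserstein OFF-HIGH: %.2f to %.2f (largest: %s, %s %s)",
      min(hi$wasserstein), max(hi$wasserstein), top$vial, top$sequence,
      top$session))
  }

  ft <- results$feature_tests
  if (is.null(ft) || !nrow(ft)) {
    lines <- c(lines, "", "No feature tests available; significance matrix omitted.")
  } else {
    wide <- stats::reshape(
      ft[, c("sequence", "session", "feature", "level", "wilcoxon_p")],
      idvar = c("sequence", "session", "feature"), timevar = "level",
      direction = "wide")
    names(wide) <- sub("^wilcoxon_p\\.", "p_OFF_", names(wide))
    wide <- wide[order(wide$sequence, wide$session, wide$feature), ]
    utils::write.csv(wide, file.path(out_dir, "significance_matrix.csv"),
                     row.names = FALSE)
    nsig <- sum(ft$wilcoxon_p < 0.05)
    lines <- c(lines, sprintf(
      "Wilcoxon: %d of %d feature x level x session comparisons significant at p < 0.05",
      nsig, nrow(ft)))
  }
  writeLines(lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
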