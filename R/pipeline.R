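# Configuration-driven pipeline: simulate -> fit -> extract -> analyze ->
# report. Each (session, repeat) raw acquisition is simulated once, all
# reconstruction levels are derived from it, fitted, and reduced to per-VOI
# ADC samples immediately, so memory stays flat in the study size.

LEVEL_PAIRS <- c("LOW", "MEDIUM", "HIGH")

#' Default pipeline configuration
#'
#' @param sequences character vector, subset of `c("fFOV", "rFOV")`.
#' @param seed integer base seed.
#' @param ... named overrides merged into the config (see
#'   [validate_config()] for recognized keys).
#' @return A named list (pipeline config).
#' @export
default_config <- function(sequences = c("fFOV", "rFOV"), seed = 20260413L, ...) {
  cfg <- list(
    sequences = sequences,
    seed = as.integer(seed),
    protocol = list(),
    design = list(),
    layout = list(),
    histogram = list(bin_width = 5e-6),
    keep_intermediates = FALSE,
    out_dir = NULL
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and checks field types before any stage runs.
#'
#' @param cfg named list as produced by [default_config()] or read from a
#'   JSON config file.
#' @return The validated config (with defaults filled in).
#' @export
validate_config <- function(cfg) {
  known <- c("sequences", "seed", "protocol", "design", "layout",
             "histogram", "keep_intermediates", "out_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stopf("unknown config keys: %s",
                             paste(unknown, collapse = ", "))
  cfg$sequences <- match.arg(cfg$sequences %||% c("fFOV", "rFOV"),
                             c("fFOV", "rFOV"), several.ok = TRUE)
  cfg$seed <- as.integer(cfg$seed %||% 20260413L)
  cfg$protocol <- cfg$protocol %||% list()
  cfg$design <- cfg$design %||% list()
  cfg$layout <- cfg$layout %||% list()
  cfg$histogram <- cfg$histogram %||% list(bin_width = 5e-6)
  cfg$keep_intermediates <- isTRUE(cfg$keep_intermediates)
  dknown <- c("levels", "n_repeats", "sessions")
  dunknown <- setdiff(names(cfg$design), dknown)
  if (length(dunknown)) stopf("unknown design keys: %s",
                              paste(dunknown, collapse = ", "))
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file; same keys as [default_config()].
#' @return Validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$design$sessions))
    cfg$design$sessions <- as.data.frame(cfg$design$sessions)
  if (!is.null(cfg$design$levels))
    cfg$design$levels <- unlist(cfg$design$levels)
  validate_config(cfg)
}

config_design <- function(cfg) {
  d <- cfg$design
  default_study_design(
    levels = d$levels %||% c(OFF = 0, LOW = 0.4, MEDIUM = 0.8, HIGH = 1.2),
    n_repeats = d$n_repeats %||% 5L,
    sessions = d$sessions %||% data.frame(session = c("S1", "S2"),
                                          temperature_c = c(22.9, 20.8)),
    base_seed = cfg$seed)
}

config_protocol <- function(cfg, sequence) {
  do.call(default_protocol, c(list(sequence = sequence), cfg$protocol))
}

# Analyze one sequence end to end; returns the per-sequence result tables.
analyze_sequence <- function(sequence, design, protocol, layout, model,
                             bin_width = 5e-6, keep_intermediates = FALSE,
                             out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf("[%s] ", sequence), sprintf(...))
  levels <- names(design$levels)
  grid_dims <- c(protocol$matrix, protocol$matrix, protocol$n_slices)
  vois <- default_voi_specs(layout, protocol$n_slices)
  masks <- lapply(seq_len(nrow(vois)), function(i)
    make_cylindrical_voi(vois[i, ], grid_dims, protocol$pixel_mm))
  names(masks) <- vois$label
  say("built %d VOI masks (%d voxels each)", length(masks),
      masks[[1]]$voxel_count)

  # raw per-VOI value vectors (NA kept for voxel pairing):
  # vals[[session]][[vial]][[level]][[repeat]]
  vals <- list()
  per_repeat <- list()
  for (s in seq_len(nrow(design$sessions))) {
    ses <- design$sessions$session[s]
    temp <- design$sessions$temperature_c[s]
    truth <- NULL
    for (r in seq_len(design$n_repeats)) {
      seed <- derive_seed(design$base_seed, s, r)
      raw <- simulate_dwi_series(layout, protocol, model, temp,
                                 seed = seed, repeat_id = r, session_id = ses)
      truth <- raw$ground_truth
      say("session %s repeat %d simulated (seed %d)", ses, r, seed)
      for (lv in levels) {
        stack <- emulate_dl_reconstruction(raw, lv, design$levels)
        map <- fit_adc_map(stack)
        if (keep_intermediates && !is.null(out_dir)) {
          dir.create(file.path(out_dir, "maps"), showWarnings = FALSE,
                     recursive = TRUE)
          write_nifti(map$values,
                      file.path(out_dir, "maps",
                                sprintf("adc_%s_%s_r%d_%s.nii",
                                        sequence, ses, r, lv)),
                      pixdim = c(map$pixel_mm, map$pixel_mm, map$slice_mm),
                      descrip = "ADC map (mm^2/s)")
        }
        for (lab in vois$label) {
          v <- map$values[masks[[lab]]$mask]
          vals[[ses]][[lab]][[lv]][[r]] <- v
          per_repeat[[length(per_repeat) + 1]] <- data.frame(
            sequence = sequence, session = ses, vial = lab, level = lv,
            repeat_id = r, median_adc = stats::median(v, na.rm = TRUE),
            nominal_adc = truth[[lab]])
        }
      }
    }
  }
  per_repeat <- do.call(rbind, per_repeat)
  per_repeat$deviation_percent <-
    percent_deviation(per_repeat$median_adc, per_repeat$nominal_adc)

  # accuracy: repeat medians averaged within session, then deviation
  accuracy <- do.call(rbind, lapply(
    split(per_repeat, list(per_repeat$session, per_repeat$vial,
                           per_repeat$level), drop = TRUE),
    function(g) data.frame(
      sequence = sequence, session = g$session[1], vial = g$vial[1],
      level = g$level[1], measured_median = mean(g$median_adc),
      nominal = g$nominal_adc[1],
      deviation_percent = percent_deviation(mean(g$median_adc),
                                            g$nominal_adc[1]))))

  repeatability <- do.call(rbind, lapply(
    split(per_repeat, list(per_repeat$session, per_repeat$vial,
                           per_repeat$level), drop = TRUE),
    function(g) {
      g <- g[order(g$repeat_id), ]
      md <- max_percent_deviation(g$median_adc)
      data.frame(sequence = sequence, session = g$session[1],
                 vial = g$vial[1], level = g$level[1],
                 cv_percent = coefficient_of_variation(g$median_adc),
                 max_dev_neg = md[["neg"]], max_dev_pos = md[["pos"]])
    }))

  # histogram analysis per (session, vial): shared spec pooled over levels
  # and repeats, per-repeat features, mean histograms, Wasserstein, Friedman
  comparisons <- list()
  friedman <- list()
  features <- list()
  for (ses in design$sessions$session) {
    for (lab in vois$label) {
      byl <- vals[[ses]][[lab]]
      finite_pool <- unlist(byl, use.names = FALSE)
      spec <- build_shared_spec(list(finite_pool[is.finite(finite_pool)]),
                                bin_width = bin_width)
      mean_h <- list()
      for (lv in levels) {
        hs <- lapply(byl[[lv]], function(v) compute_histogram(v[is.finite(v)], spec))
        mean_h[[lv]] <- mean_histogram(hs)
        for (r in seq_along(byl[[lv]])) {
          fv <- compute_features(byl[[lv]][[r]][is.finite(byl[[lv]][[r]])], spec)
          features[[length(features) + 1]] <- data.frame(
            sequence = sequence, session = ses, vial = lab, level = lv,
            repeat_id = r, feature = names(fv), value = as.numeric(fv))
        }
      }
      for (lv in setdiff(levels, levels[1])) {
        comparisons[[length(comparisons) + 1]] <- data.frame(
          sequence = sequence, session = ses, vial = lab, level = lv,
          wasserstein = wasserstein_distance(mean_h[[levels[1]]], mean_h[[lv]]))
      }
      # voxel-paired Friedman: repeats concatenated, rows complete across levels
      X <- do.call(cbind, lapply(levels, function(lv)
        unlist(byl[[lv]], use.names = FALSE)))
      X <- X[stats::complete.cases(X), , drop = FALSE]
      fr <- friedman_across_levels(asplit(X, 2))
      friedman[[length(friedman) + 1]] <- data.frame(
        sequence = sequence, session = ses, vial = lab,
        statistic = fr$statistic, df = fr$df, p = fr$p,
        degenerate = fr$degenerate)
    }
  }
  comparisons <- do.call(rbind, comparisons)
  friedman <- do.call(rbind, friedman)
  features <- do.call(rbind, features)

  # per-(vial, session, level) feature = mean over repeats
  feat_cell <- stats::aggregate(value ~ sequence + session + vial + level + feature,
                                data = features, FUN = mean)

  # percent differences vs OFF, per vial and session
  off <- feat_cell[feat_cell$level == levels[1], ]
  names(off)[names(off) == "value"] <- "off_value"
  off$level <- NULL
  dl <- feat_cell[feat_cell$level != levels[1], ]
  fd <- merge(dl, off, by = c("sequence", "session", "vial", "feature"))
  fd$percent_difference <- percent_difference(fd$off_value, fd$value)
  feature_diffs <- fd[, c("sequence", "session", "vial", "level", "feature",
                          "percent_difference")]

  # Wilcoxon: paired over (vial x repeat) per session, feature, level pair
  feature_tests <- list()
  for (ses in design$sessions$session) {
    fs <- features[features$session == ses, ]
    for (feat in FEATURE_NAMES) {
      f0 <- fs[fs$feature == feat & fs$level == levels[1], ]
      f0 <- f0[order(f0$vial, f0$repeat_id), ]
      for (lv in setdiff(levels, levels[1])) {
        f1 <- fs[fs$feature == feat & fs$level == lv, ]
        f1 <- f1[order(f1$vial, f1$repeat_id), ]
        keep <- is.finite(f0$value) & is.finite(f1$value)
        wt <- wilcoxon_paired(f0$value[keep], f1$value[keep])
        feature_tests[[length(feature_tests) + 1]] <- data.frame(
          sequence = sequence, session = ses, feature = feat, level = lv,
          n_pairs = wt$n, wilcoxon_p = wt$p, degenerate = wt$degenerate)
      }
    }
  }
  feature_tests <- do.call(rbind, feature_tests)

  out <- list(per_repeat = per_repeat, accuracy = accuracy,
              repeatability = repeatability, comparisons = comparisons,
              friedman = friedman, features = features,
              feature_diffs = feature_diffs, feature_tests = feature_tests)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Run the full phantom study pipeline
#'
#' Simulates the configured study for each sequence, fits ADC maps, extracts
#' VOI samples, and computes every report table: accuracy, repeatability,
#' Wasserstein comparisons, Friedman tests, per-repeat first-order features,
#' percent differences, and paired Wilcoxon tests, plus cross-session pooled
#' summaries when two or more sessions are configured. Re-running with an
#' identical config reproduces identical outputs.
#'
#' @param config pipeline config from [default_config()] or
#'   [read_pipeline_config()].
#' @param out_dir optional output directory; when given, all tables are
#'   written as CSV together with a JSON run manifest.
#' @param model optional `nominal_adc_model` (default [default_adc_model()]).
#' @param verbose emit stage-tagged progress messages.
#' @return A `study_result_set`: list of tidy data.frames (`accuracy`,
#'   `repeatability`, `per_repeat`, `comparisons`, `friedman`, `features`,
#'   `feature_diffs`, `feature_tests`, `pooled`, `meta`).
#' @export
run_study <- function(config = default_config(), out_dir = NULL,
                      model = NULL, verbose = FALSE) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  model <- model %||% default_adc_model()
  design <- config_design(config)
  parts <- lapply(config$sequences, function(sq) {
    proto <- config_protocol(config, sq)
    lay_cfg <- config$layout
    # layout FOV follows the protocol grid unless explicitly overridden
    lay_cfg$fov_mm <- lay_cfg$fov_mm %||% (proto$matrix * proto$pixel_mm)
    analyze_sequence(sq, design,
                     protocol = proto,
                     layout = build_phantom_layout(sq, lay_cfg),
                     model = model,
                     bin_width = config$histogram$bin_width %||% 5e-6,
                     keep_intermediates = config$keep_intermediates,
                     out_dir = out_dir, verbose = verbose)
  })
  tables <- names(parts[[1]])
  res <- stats::setNames(lapply(tables, function(tb)
    do.call(rbind, lapply(parts, `[[`, tb))), tables)

  res$pooled <- if (nrow(design$sessions) >= 2) aggregate_sessions(res) else NULL
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  res$meta <- list(seed = config$seed, config = config,
                   config_hash = fnv1a32(as.character(cfg_json)),
                   package_version = as.character(utils::packageVersion("adcphantom")))
  class(res) <- "study_result_set"

  if (!is.null(out_dir)) write_result_csvs(res, out_dir)
  res
}

write_result_csvs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(res$accuracy, "accuracy.csv")
  wcsv(res$repeatability, "repeatability.csv")
  wcsv(res$per_repeat, "per_repeat.csv")
  wcsv(res$comparisons, "wasserstein.csv")
  wcsv(res$friedman, "friedman.csv")
  wcsv(res$features, "features.csv")
  wcsv(res$feature_diffs, "percent_diff.csv")
  wcsv(res$feature_tests, "wilcoxon.csv")
  if (!is.null(res$pooled)) {
    wcsv(res$pooled$accuracy_pooled, "pooled_accuracy.csv")
    wcsv(res$pooled$cv_pooled, "pooled_cv.csv")
    wcsv(res$pooled$maxdev_pooled, "pooled_maxdev.csv")
    wcsv(res$pooled$wasserstein_pooled, "pooled_wasserstein.csv")
    wcsv(res$pooled$percent_diff_pooled, "pooled_percent_diff.csv")
  }
  jsonlite::write_json(
    list(seed = res$meta$seed, config = res$meta$config,
         config_hash = res$meta$config_hash,
         package_version = res$meta$package_version),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(data_dictionary_text(), file.path(out_dir, "data_dictionary.txt"))
  invisible(out_dir)
}

data_dictionary_text <- function() {
  c("adcphantom output tables",
    "",
    "accuracy.csv        one row per sequence x session x vial x level;",
    "                    measured_median = VOI median ADC averaged over repeats (mm^2/s);",
    "                    deviation_percent = 100*(measured-nominal)/nominal",
    "repeatability.csv   cv_percent = 100*sd/mean of repeat medians;",
    "                    max_dev_neg/pos = extreme % deviations from repeat 1",
    "per_repeat.csv      per-repeat VOI median ADC and its % deviation",
    "wasserstein.csv     distance between OFF and each level's mean histogram,",
    "                    bin-index units (sum |CDF1 - CDF2| over shared bins)",
    "friedman.csv        voxel-paired Friedman chi-square across all levels",
    "features.csv        eleven first-order features per vial/level/repeat/session",
    "percent_diff.csv    per-vial % difference of repeat-averaged features vs OFF",
    "wilcoxon.csv        paired Wilcoxon p per feature/level/session,",
    "                    pairing unit = vial x repeat",
    "pooled_*.csv        cross-session aggregation: CV and Wasserstein averaged,",
    "                    max deviations extrema, accuracy median/IQR over pooled",
    "                    per-repeat deviations, percent diffs mean/SD over",
    "                    vial x session cells")
}

#' @export
print.study_result_set <- function(x, ...) {
  cat(sprintf("<study_result_set> sequences: %s; %d accuracy cells, %d feature tests\n",
              paste(unique(x$accuracy$sequence), collapse = ", "),
              nrow(x$accuracy), nrow(x$feature_tests)))
  invisible(x)
}
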