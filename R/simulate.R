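# Synthetic DWI acquisition of the phantom.
#
# Signal chain: noiseless mono-exponential decay S(b) = S0 * exp(-b * ADC)
# per voxel (vial ADC inside vials, bath ADC in the surrounding water, zero
# signal outside the phantom), then per b-value the stored image is the
# arithmetic mean of `averages_per_b` independent Rician magnitude
# realizations — magnitude-domain NEX averaging, which preserves the Rician
# noise floor the downstream analysis is sensitive to.

# ADC and S0 fields on the protocol grid, from vial membership.
phantom_fields <- function(layout, protocol, model, temperature_c) {
  n <- protocol$matrix
  px <- protocol$pixel_mm
  xc <- (seq_len(n) - 0.5) * px
  X <- matrix(xc, n, n)
  Y <- matrix(xc, n, n, byrow = TRUE)
  cx <- layout$fov_mm / 2

  adc <- matrix(NA_real_, n, n)
  bath <- (X - cx)^2 + (Y - cx)^2 <= layout$bath_radius_mm^2
  adc[bath] <- layout$bath_adc

  vis <- layout$vials[layout$vials$label %in% layout$visible_labels, , drop = FALSE]
  truth <- stats::setNames(
    nominal_adc(model, vis$pvp_fraction, temperature_c), vis$label)
  for (i in seq_len(nrow(vis))) {
    inside <- (X - vis$x_mm[i])^2 + (Y - vis$y_mm[i])^2 < vis$radius_mm[i]^2
    adc[inside] <- truth[[vis$label[i]]]
  }
  s0 <- matrix(0, n, n)
  s0[bath] <- protocol$s0
  list(adc = adc, s0 = s0, ground_truth = truth)
}

#' Simulate one multi-b DWI acquisition of the phantom
#'
#' @param layout a `phantom_layout`.
#' @param protocol an `acquisition_protocol`.
#' @param model a `nominal_adc_model` providing the true vial ADCs.
#' @param temperature_c phantom temperature (C) at acquisition time.
#' @param seed integer RNG seed; identical seeds give bit-identical stacks.
#' @param noise if `FALSE`, or if `protocol$noise_sigma == 0`, the noiseless
#'   decay is returned directly.
#' @return A `dwi_stack`: list with `data` (4D array x, y, slice, b-index),
#'   `protocol`, `level` (`"RAW"`), `repeat_id`, `session_id`, `ground_truth`.
#' @export
simulate_dwi_series <- function(layout, protocol, model, temperature_c,
                                seed = 1L, noise = TRUE,
                                repeat_id = 1L, session_id = "S1") {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(protocol, "acquisition_protocol"))
  f <- phantom_fields(layout, protocol, model, temperature_c)
  n <- protocol$matrix
  nz <- protocol$n_slices
  b <- protocol$b_values
  nb <- length(b)
  sigma <- protocol$noise_sigma
  use_noise <- isTRUE(noise) && sigma > 0
  if (isTRUE(noise) && sigma < 0) stopf("noise_sigma must be positive when noise is enabled")

  adc0 <- f$adc
  adc0[is.na(adc0)] <- 0

  data <- array(0, dim = c(n, n, nz, nb))
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  for (k in seq_len(nb)) {
    s_plane <- f$s0 * exp(-b[k] * adc0)          # zero outside phantom
    if (!use_noise) {
      data[, , , k] <- array(rep(s_plane, nz), dim = c(n, n, nz))
    } else {
      nav <- protocol$averages_per_b[k]
      acc <- array(0, dim = c(n, n, nz))
      s_vol <- array(rep(s_plane, nz), dim = c(n, n, nz))
      for (a in seq_len(nav)) {
        re <- s_vol + array(stats::rnorm(n * n * nz, sd = sigma), dim = dim(s_vol))
        im <- array(stats::rnorm(n * n * nz, sd = sigma), dim = dim(s_vol))
        acc <- acc + sqrt(re^2 + im^2)
      }
      data[, , , k] <- acc / nav
    }
  }
  structure(list(data = data, protocol = protocol, level = "RAW",
                 repeat_id = repeat_id, session_id = session_id,
                 temperature_c = temperature_c,
                 ground_truth = f$ground_truth),
            class = "dwi_stack")
}

# Row-normalized banded Gaussian convolution matrix. Rows truncated at the
# image border are renormalized, so constants are preserved exactly.
gaussian_band_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  w <- stats::dnorm(seq(-r, r), sd = sigma_px)
  M <- matrix(0, n, n)
  for (k in seq(-r, r)) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + w[k + r + 1L]
  }
  M / rowSums(M)
}

#' Emulate reconstruction-stage denoising at a given strength
#'
#' A parametric stand-in for vendor DL denoising: each in-plane b-value
#' image is convolved with an isotropic Gaussian kernel whose standard
#' deviation in mm is the level's smoothing parameter. `OFF` (smoothing 0)
#' returns the input unchanged.
#'
#' @param stack a `dwi_stack`.
#' @param level level name, one of `names(levels)`.
#' @param levels named vector of smoothing SDs (mm); defaults to the
#'   package's OFF/LOW/MEDIUM/HIGH ladder.
#' @return A `dwi_stack` with smoothed data and `level` set.
#' @export
emulate_dl_reconstruction <- function(stack, level,
                                      levels = c(OFF = 0, LOW = 0.4,
                                                 MEDIUM = 0.8, HIGH = 1.2)) {
  stopifnot(inherits(stack, "dwi_stack"))
  if (!level %in% names(levels)) stopf("unknown reconstruction level '%s'", level)
  sigma_mm <- levels[[level]]
  out <- stack
  out$level <- level
  if (sigma_mm == 0) return(out)
  sigma_px <- sigma_mm / stack$protocol$pixel_mm
  dm <- dim(stack$data)
  M <- gaussian_band_matrix(dm[1], sigma_px)
  Mt <- t(gaussian_band_matrix(dm[2], sigma_px))
  for (z in seq_len(dm[3])) for (k in seq_len(dm[4])) {
    out$data[, , z, k] <- M %*% stack$data[, , z, k] %*% Mt
  }
  out$data[out$data < 0] <- 0
  out
}

#' Simulate a full repeatability study for one sequence
#'
#' For each (session, repeat) one raw noisy acquisition is generated with a
#' seed derived deterministically from the design's base seed; every
#' reconstruction level is then produced from that same raw realization,
#' mirroring multiple reconstructions of a single scan and making paired
#' statistics across levels meaningful.
#'
#' @param design a `study_design`.
#' @param sequence `"fFOV"` or `"rFOV"`.
#' @param protocol,layout,model optional overrides; defaults derived from
#'   `sequence`.
#' @return Named list of `dwi_stack`s keyed `"<session>_r<repeat>_<level>"`.
#' @export
simulate_study <- function(design, sequence = c("fFOV", "rFOV"),
                           protocol = NULL, layout = NULL, model = NULL) {
  sequence <- match.arg(sequence)
  stopifnot(inherits(design, "study_design"))
  protocol <- protocol %||% default_protocol(sequence)
  layout <- layout %||% build_phantom_layout(sequence)
  model <- model %||% default_adc_model()
  out <- list()
  for (s in seq_len(nrow(design$sessions))) {
    ses <- design$sessions$session[s]
    temp <- design$sessions$temperature_c[s]
    for (r in seq_len(design$n_repeats)) {
      seed <- derive_seed(design$base_seed, s, r)
      raw <- simulate_dwi_series(layout, protocol, model, temp,
                                 seed = seed, repeat_id = r, session_id = ses)
      for (lv in names(design$levels)) {
        out[[sprintf("%s_r%d_%s", ses, r, lv)]] <-
          emulate_dl_reconstruction(raw, lv, design$levels)
      }
    }
  }
  out
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_stack> %s %s session=%s repeat=%s grid %dx%dx%d, %d b-values\n",
              x$protocol$sequence, x$level, x$session_id, x$repeat_id,
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Write ground truth and layout geometry as JSON
#'
#' @param stack a `dwi_stack` with populated `ground_truth`.
#' @param layout the `phantom_layout` used for simulation.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(stack, layout, path) {
  stopifnot(inherits(stack, "dwi_stack"), inherits(layout, "phantom_layout"))
  jsonlite::write_json(
    list(true_adc = as.list(stack$ground_truth),
         temperature_c = stack$temperature_c,
         vials = layout$vials,
         bath_adc = layout$bath_adc,
         bath_radius_mm = layout$bath_radius_mm,
         fov_mm = layout$fov_mm,
         visible_labels = layout$visible_labels),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
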