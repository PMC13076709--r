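# Acquisition protocol and study design containers.

#' Default DWI acquisition protocol
#'
#' Five b-values (0, 500, 1000, 1500, 2000 s/mm^2). The full-FOV protocol
#' uses two averages at every b on a 0.86 mm grid; the reduced-FOV protocol
#' trades coverage for 0.70 mm resolution and compensates its lower SNR with
#' four averages at the diffusion-weighted b-values.
#'
#' @param sequence `"fFOV"` or `"rFOV"`.
#' @param ... overrides for any protocol field (`matrix`, `n_slices`,
#'   `pixel_mm`, `slice_mm`, `noise_sigma`, `s0`, `b_values`,
#'   `averages_per_b`, `signal_floor_sigma`).
#' @return An `acquisition_protocol` list.
#' @export
default_protocol <- function(sequence = c("fFOV", "rFOV"), ...) {
  sequence <- match.arg(sequence)
  p <- if (sequence == "fFOV") {
    list(sequence = "fFOV", b_values = c(0, 500, 1000, 1500, 2000),
         averages_per_b = c(2L, 2L, 2L, 2L, 2L),
         pixel_mm = 0.86, slice_mm = 4, matrix = 256L, n_slices = 25L,
         noise_sigma = 4, s0 = 1000, signal_floor_sigma = 3)
  } else {
    list(sequence = "rFOV", b_values = c(0, 500, 1000, 1500, 2000),
         averages_per_b = c(2L, 4L, 4L, 4L, 4L),
         pixel_mm = 0.70, slice_mm = 3, matrix = 256L, n_slices = 27L,
         noise_sigma = 4, s0 = 1000, signal_floor_sigma = 3)
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stopf("unknown protocol fields: %s",
                             paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  validate_protocol(structure(p, class = "acquisition_protocol"))
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "acquisition_protocol"))
  b <- p$b_values
  if (length(b) < 2 || b[1] != 0 || any(diff(b) <= 0))
    stopf("b_values must be strictly increasing and start at 0")
  if (length(p$averages_per_b) != length(b) || any(p$averages_per_b < 1))
    stopf("averages_per_b must align with b_values and be positive")
  if (p$pixel_mm <= 0 || p$slice_mm <= 0 || p$matrix < 8 || p$n_slices < 1)
    stopf("invalid grid geometry")
  if (p$noise_sigma < 0) stopf("noise_sigma must be >= 0")
  p
}

#' Default study design
#'
#' Four reconstruction strengths (OFF/LOW/MEDIUM/HIGH) emulated as in-plane
#' Gaussian smoothing with standard deviations 0 / 0.4 / 0.8 / 1.2 mm, five
#' repeats per session, and two sessions a month apart at slightly different
#' phantom temperatures.
#'
#' @param levels named numeric vector of smoothing standard deviations (mm),
#'   in increasing strength order; first entry must be exactly 0.
#' @param n_repeats repeats per session (>= 2).
#' @param sessions data.frame with columns `session` and `temperature_c`.
#' @param base_seed integer seed from which per-acquisition seeds derive.
#' @return A `study_design` list.
#' @export
default_study_design <- function(levels = c(OFF = 0, LOW = 0.4, MEDIUM = 0.8, HIGH = 1.2),
                                 n_repeats = 5L,
                                 sessions = data.frame(
                                   session = c("S1", "S2"),
                                   temperature_c = c(22.9, 20.8)),
                                 base_seed = 20260413L) {
  if (is.null(names(levels)) || any(names(levels) == ""))
    stopf("levels must be a named vector")
  if (levels[[1]] != 0) stopf("first level must have smoothing 0 (OFF)")
  if (any(diff(levels) <= 0)) stopf("smoothing must be strictly increasing across levels")
  if (n_repeats < 2) stopf("n_repeats must be >= 2")
  stopifnot(is.data.frame(sessions),
            all(c("session", "temperature_c") %in% names(sessions)))
  structure(list(levels = levels, n_repeats = as.integer(n_repeats),
                 sessions = sessions, base_seed = as.integer(base_seed)),
            class = "study_design")
}
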