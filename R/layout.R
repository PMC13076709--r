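# Phantom geometry: thirteen 20 mL vials of six PVP concentrations arranged
# as one central vial plus inner and outer rings of six, immersed in a water
# bath. Coordinates are physical millimetres with the origin at the corner
# of the field of view and the phantom centred on the FOV centre.

VIAL_RADIUS_MM <- 16      # vial cross-section radius; leaves margin around VOIs
INNER_RING_MM <- 33       # inner ring radius (vial centres)
OUTER_RING_MM <- 59       # outer ring radius (vial centres)
BATH_RADIUS_MM <- 85      # water bath disc radius

RECON_LEVELS <- c("OFF", "LOW", "MEDIUM", "HIGH")

# Concentration per position. Central vial is water; inner ring carries all
# six concentrations; outer ring carries all six. The two outer vials absent
# from the reduced-FOV table (20% and 50%) are the ones cropped when the
# phantom is rotated into the smaller FOV.
vial_table <- function() {
  conc <- c(0, PVP_FRACTIONS, PVP_FRACTIONS)
  ring <- c("central", rep("inner", 6), rep("outer", 6))
  label <- sprintf("PVP%d_%s", round(conc * 100),
                   c("C", rep("I", 6), rep("O", 6)))
  data.frame(label = label, pvp_fraction = conc, ring = ring,
             stringsAsFactors = FALSE)
}

#' Build the default phantom layout for a sequence
#'
#' Returns the 13-vial layout (full-FOV) or the same layout with the two
#' cropped outer vials marked invisible (reduced-FOV, 11 visible). Vials sit
#' on two concentric rings around a central vial; the outer ring is rotated
#' by 30 degrees relative to the inner ring for packing.
#'
#' @param sequence `"fFOV"` or `"rFOV"`.
#' @param config optional named list of overrides: `fov_mm` (FOV extent),
#'   `bath_adc` (mm^2/s), `vial_radius_mm`, `inner_ring_mm`, `outer_ring_mm`,
#'   `vials` (a complete replacement data.frame with columns label,
#'   pvp_fraction, ring, x_mm, y_mm, radius_mm), `visible_labels`.
#' @return A `phantom_layout`: list with `vials` (data.frame: label,
#'   pvp_fraction, ring, x_mm, y_mm, radius_mm), `bath_adc`, `bath_radius_mm`,
#'   `fov_mm`, `visible_labels`, `sequence`.
#' @export
build_phantom_layout <- function(sequence = c("fFOV", "rFOV"), config = list()) {
  sequence <- match.arg(sequence)
  stopifnot(is.list(config))
  fov <- config$fov_mm %||% if (sequence == "fFOV") 220.16 else 179.2
  r_v <- config$vial_radius_mm %||% VIAL_RADIUS_MM
  r1 <- config$inner_ring_mm %||% INNER_RING_MM
  r2 <- config$outer_ring_mm %||% OUTER_RING_MM

  if (!is.null(config$vials)) {
    v <- config$vials
    need <- c("label", "pvp_fraction", "ring", "x_mm", "y_mm", "radius_mm")
    if (!all(need %in% names(v))) stopf("vials override needs columns %s",
                                        paste(need, collapse = ", "))
  } else {
    v <- vial_table()
    cx <- fov / 2
    ang_in <- (seq_len(6) - 1) * pi / 3
    ang_out <- ang_in + pi / 6
    v$x_mm <- cx + c(0, r1 * cos(ang_in), r2 * cos(ang_out))
    v$y_mm <- cx + c(0, r1 * sin(ang_in), r2 * sin(ang_out))
    v$radius_mm <- r_v
  }
  if (anyDuplicated(v$label)) stopf("vial labels must be unique")

  # pairwise overlap check
  if (nrow(v) > 1) {
    d <- as.matrix(stats::dist(v[, c("x_mm", "y_mm")]))
    rsum <- outer(v$radius_mm, v$radius_mm, `+`)
    diag(d) <- Inf
    if (any(d < rsum)) stopf("phantom layout has overlapping vials")
  }

  visible <- config$visible_labels %||%
    if (sequence == "rFOV") setdiff(v$label, c("PVP20_O", "PVP50_O")) else v$label
  if (!all(visible %in% v$label)) stopf("visible_labels not all present in layout")

  structure(list(
    vials = v,
    bath_adc = config$bath_adc %||% 2.0e-3,
    bath_radius_mm = config$bath_radius_mm %||% BATH_RADIUS_MM,
    fov_mm = fov,
    visible_labels = visible,
    sequence = sequence
  ), class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %s: %d vials (%d visible), FOV %.1f mm\n",
              x$sequence, nrow(x$vials), length(x$visible_labels), x$fov_mm))
  invisible(x)
}
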