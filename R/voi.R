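# Cylindrical volumes of interest at vial centres.
#
# A VOI is a circle of fixed diameter drawn on `n_slices` consecutive
# slices and centred in a vial: 25 mm diameter for the full-FOV sequence,
# 22 mm for reduced-FOV (smaller to keep clear of edge effects). Masks are
# built once per sequence and reused identically across all reconstruction
# levels and repeats so that segmentation never contributes variability.

#' Default VOI specifications for a phantom layout
#'
#' One cylindrical VOI per visible vial, centred on the vial, with the
#' sequence's standard diameter, three slices, centred in the slice stack.
#'
#' @param layout a `phantom_layout`.
#' @param n_slices_grid number of slices in the target grid (to centre the
#'   3-slice block).
#' @param diameter_mm override of the VOI diameter; defaults 25 (fFOV) or
#'   22 (rFOV).
#' @param n_slices slices per VOI (default 3, capped at the grid size).
#' @return data.frame: label, x_mm, y_mm, diameter_mm, n_slices, start_slice.
#' @export
default_voi_specs <- function(layout, n_slices_grid,
                              diameter_mm = NULL, n_slices = 3L) {
  stopifnot(inherits(layout, "phantom_layout"))
  d <- diameter_mm %||% if (layout$sequence == "fFOV") 25 else 22
  n_slices <- min(as.integer(n_slices), n_slices_grid)
  start <- max(1L, as.integer(ceiling(n_slices_grid / 2)) - (n_slices %/% 2))
  v <- layout$vials[layout$vials$label %in% layout$visible_labels, , drop = FALSE]
  data.frame(label = v$label, x_mm = v$x_mm, y_mm = v$y_mm,
             diameter_mm = d, n_slices = n_slices, start_slice = start,
             stringsAsFactors = FALSE)
}

#' Build a cylindrical VOI mask on an image grid
#'
#' A voxel is included iff its centre lies strictly within `diameter_mm / 2`
#' of the VOI centre in-plane, on `n_slices` consecutive slices starting at
#' `start_slice`. Voxel centres sit at `(i - 0.5) * pixel_mm` with the
#' origin at the FOV corner.
#'
#' @param spec one-row data.frame or list with `x_mm`, `y_mm`,
#'   `diameter_mm`, `n_slices`, `start_slice`.
#' @param dims integer vector `c(nx, ny, nz)` of the grid.
#' @param pixel_mm in-plane spacing.
#' @return A `voi_mask`: list with `mask` (3D logical) and `voxel_count`.
#' @export
make_cylindrical_voi <- function(spec, dims, pixel_mm) {
  r <- spec$diameter_mm / 2
  if (r <= 0) stopf("VOI diameter must be positive")
  z0 <- as.integer(spec$start_slice)
  z1 <- z0 + as.integer(spec$n_slices) - 1L
  if (z0 < 1 || z1 > dims[3]) stopf("VOI slice block outside grid")
  if (spec$x_mm - r < 0 || spec$x_mm + r > dims[1] * pixel_mm ||
      spec$y_mm - r < 0 || spec$y_mm + r > dims[2] * pixel_mm)
    stopf("VOI cylinder exceeds grid bounds")
  xc <- (seq_len(dims[1]) - 0.5) * pixel_mm
  yc <- (seq_len(dims[2]) - 0.5) * pixel_mm
  inplane <- outer((xc - spec$x_mm)^2, (yc - spec$y_mm)^2, `+`) < r^2
  mask <- array(FALSE, dim = dims)
  for (z in z0:z1) mask[, , z] <- inplane
  cnt <- sum(mask)
  if (cnt == 0) stopf("VOI mask is empty (diameter below voxel size?)")
  structure(list(mask = mask, voxel_count = cnt), class = "voi_mask")
}

#' Extract the ADC sample of a VOI from an ADC map
#'
#' Returns the ADC values at mask positions, dropping voxels where the map
#' is missing.
#'
#' @param map an `adc_map`.
#' @param mask a `voi_mask` on the same grid.
#' @param label optional vial label carried into provenance.
#' @return An `adc_sample`: list with `values` (numeric vector) and
#'   `provenance`.
#' @export
extract_adc_sample <- function(map, mask, label = NULL) {
  stopifnot(inherits(map, "adc_map"), inherits(mask, "voi_mask"))
  if (!identical(dim(map$values), dim(mask$mask)))
    stopf("mask grid %s does not match map grid %s",
          paste(dim(mask$mask), collapse = "x"),
          paste(dim(map$values), collapse = "x"))
  vals <- map$values[mask$mask]
  vals <- vals[is.finite(vals)]
  prov <- map$provenance
  prov$vial <- label
  structure(list(values = vals, provenance = prov), class = "adc_sample")
}
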