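brute_force_count <- function(center, radius_mm, dims, pixel_mm) {
  cnt <- 0
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    x <- (i - 0.5) * pixel_mm
    y <- (j - 0.5) * pixel_mm
    if ((x - center[1])^2 + (y - center[2])^2 < radius_mm^2) cnt <- cnt + 1
  }
  cnt
}

test_that("cylindrical masks match brute-force voxel-center enumeration", {
  px <- 0.86
  spec <- data.frame(x_mm = 20.5 * px, y_mm = 20.5 * px,  # on a voxel center
                     diameter_mm = 2 * px, n_slices = 1, start_slice = 1)
  mk <- make_cylindrical_voi(spec, c(40, 40, 1), px)
  expect_equal(mk$voxel_count,
               brute_force_count(c(spec$x_mm, spec$y_mm), px, c(40, 40, 1), px))

  set.seed(77)
  for (i in 1:5) {
    d <- runif(1, 5, 24)
    ctr <- runif(2, 20, 25)
    spec <- data.frame(x_mm = ctr[1], y_mm = ctr[2], diameter_mm = d,
                       n_slices = 1, start_slice = 1)
    mk <- make_cylindrical_voi(spec, c(52, 52, 1), px)
    expect_equal(mk$voxel_count, brute_force_count(ctr, d / 2, c(52, 52, 1), px))
  }
})

test_that("three-slice mask is exactly three times the single-slice count", {
  spec1 <- data.frame(x_mm = 22, y_mm = 22, diameter_mm = 25,
                      n_slices = 1, start_slice = 2)
  spec3 <- data.frame(x_mm = 22, y_mm = 22, diameter_mm = 25,
                      n_slices = 3, start_slice = 1)
  m1 <- make_cylindrical_voi(spec1, c(52, 52, 3), 0.86)
  m3 <- make_cylindrical_voi(spec3, c(52, 52, 3), 0.86)
  expect_equal(m3$voxel_count, 3 * m1$voxel_count)
})

test_that("rFOV VOI has more in-plane voxels than fFOV despite smaller diameter", {
  f <- make_cylindrical_voi(data.frame(x_mm = 30, y_mm = 30, diameter_mm = 25,
                                       n_slices = 1, start_slice = 1),
                            c(68, 68, 1), 0.86)
  r <- make_cylindrical_voi(data.frame(x_mm = 30, y_mm = 30, diameter_mm = 22,
                                       n_slices = 1, start_slice = 1),
                            c(84, 84, 1), 0.70)
  expect_gt(r$voxel_count, f$voxel_count)
  # sanity: counts near pi r^2 / pixel area
  expect_equal(f$voxel_count, pi * 12.5^2 / 0.86^2, tolerance = 0.05)
  expect_equal(r$voxel_count, pi * 11^2 / 0.70^2, tolerance = 0.05)
})

test_that("geometry errors are raised for out-of-grid cylinders", {
  expect_error(make_cylindrical_voi(
    data.frame(x_mm = 5, y_mm = 30, diameter_mm = 25, n_slices = 1,
               start_slice = 1), c(68, 68, 1), 0.86), "exceeds grid")
  expect_error(make_cylindrical_voi(
    data.frame(x_mm = 30, y_mm = 30, diameter_mm = 25, n_slices = 4,
               start_slice = 1), c(68, 68, 3), 0.86), "slice block")
})

test_that("extract_adc_sample keeps defined voxels and drops missing ones", {
  map <- structure(list(values = array(1.1e-3, dim = c(10, 10, 3)),
                        pixel_mm = 1, slice_mm = 1,
                        provenance = list(level = "OFF")), class = "adc_map")
  mk <- make_cylindrical_voi(data.frame(x_mm = 5, y_mm = 5, diameter_mm = 6,
                                        n_slices = 3, start_slice = 1),
                             c(10, 10, 3), 1)
  s <- extract_adc_sample(map, mk, label = "PVP0_C")
  expect_length(s$values, mk$voxel_count)
  expect_true(all(s$values == 1.1e-3))
  expect_equal(s$provenance$vial, "PVP0_C")

  idx <- which(mk$mask)[1:2]
  map$values[idx] <- NA
  s2 <- extract_adc_sample(map, mk)
  expect_length(s2$values, mk$voxel_count - 2)

  bad <- structure(list(values = array(0, dim = c(9, 10, 3)), pixel_mm = 1,
                        slice_mm = 1, provenance = list()), class = "adc_map")
  expect_error(extract_adc_sample(bad, mk), "does not match")
})

test_that("masks are bit-identical when rebuilt (segmentation fixed across levels)", {
  lay <- compact_layout(64 * 1.8)
  vois <- default_voi_specs(lay, 5)
  m1 <- make_cylindrical_voi(vois[1, ], c(64, 64, 5), 1.8)
  m2 <- make_cylindrical_voi(vois[1, ], c(64, 64, 5), 1.8)
  expect_identical(m1, m2)
  expect_equal(vois$diameter_mm[1], 25)
  expect_equal(default_voi_specs(build_phantom_layout("rFOV"), 5)$diameter_mm[1], 22)
})
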