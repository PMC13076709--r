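test_that("noiseless simulation is the exact mono-exponential decay", {
  p <- default_protocol("fFOV", matrix = 48L, n_slices = 2L, pixel_mm = 2.5,
                        noise_sigma = 0)
  lay <- compact_layout(48 * 2.5, ring_mm = 28, bath_radius_mm = 47)
  m <- default_adc_model()
  st <- simulate_dwi_series(lay, p, m, 21, seed = 1)
  truth <- st$ground_truth
  f <- adcphantom:::phantom_fields(lay, p, m, 21)
  adc0 <- f$adc
  adc0[is.na(adc0)] <- 0
  for (k in seq_along(p$b_values)) {
    expected <- f$s0 * exp(-p$b_values[k] * adc0)
    expect_equal(st$data[, , 1, k], expected, tolerance = 1e-14)
    expect_equal(st$data[, , 2, k], expected, tolerance = 1e-14)
  }
  expect_named(truth, lay$visible_labels, ignore.order = TRUE)
})

test_that("signal-free voxels follow the Rayleigh mean", {
  # single average, pure-noise region: mean magnitude = sigma * sqrt(pi/2)
  p <- default_protocol("fFOV", matrix = 128L, n_slices = 1L, pixel_mm = 1,
                        averages_per_b = rep(1L, 5), noise_sigma = 10)
  lay <- build_phantom_layout("fFOV", config = list(
    fov_mm = 128, bath_radius_mm = 10,
    vials = data.frame(label = "PVP0_C", pvp_fraction = 0, ring = "central",
                       x_mm = 64, y_mm = 64, radius_mm = 8)))
  st <- simulate_dwi_series(lay, p, default_adc_model(), 21, seed = 42)
  xc <- (seq_len(128) - 0.5)
  far <- outer((xc - 64)^2, (xc - 64)^2, `+`) > 30^2
  expect_gt(sum(far), 1e4)
  m_obs <- mean(st$data[, , 1, 1][far])
  expect_equal(m_obs, 10 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("seeding contract: same seed identical, different seed different", {
  st1 <- small_noisy_stack(7)
  st2 <- simulate_dwi_series(compact_layout(SMALL_FOV),
    default_protocol("fFOV", matrix = SMALL_MATRIX, n_slices = 5L,
                     pixel_mm = SMALL_PX),
    default_adc_model(), 21, seed = 7)
  expect_identical(st1$data, st2$data)
  st3 <- small_noisy_stack(8)
  expect_false(identical(st1$data, st3$data))
})

test_that("denoising emulation: OFF identity, constants invariant, variance ordering", {
  st <- small_noisy_stack(7)
  off <- emulate_dl_reconstruction(st, "OFF")
  expect_identical(off$data, st$data)
  expect_identical(off$level, "OFF")

  flat <- st
  flat$data[] <- 37.5
  for (lv in c("LOW", "MEDIUM", "HIGH")) {
    sm <- emulate_dl_reconstruction(flat, lv)
    expect_equal(sm$data, flat$data, tolerance = 1e-12)
  }

  # interior variance strictly smaller at HIGH than LOW
  low <- emulate_dl_reconstruction(st, "LOW")
  high <- emulate_dl_reconstruction(st, "HIGH")
  lay <- compact_layout(SMALL_FOV)
  v0 <- lay$vials[lay$vials$label == "PVP0_C", ]
  xc <- (seq_len(SMALL_MATRIX) - 0.5) * SMALL_PX
  interior <- outer((xc - v0$x_mm)^2, (xc - v0$y_mm)^2, `+`) < (v0$radius_mm - 4)^2
  expect_gt(sum(interior) * 5, 1e3)
  var_low <- var(as.vector(low$data[, , , 1][interior]))
  var_high <- var(as.vector(high$data[, , , 1][interior]))
  expect_lt(var_high, var_low)

  # mass preservation, exact on the noiseless field: deep-interior voxels
  # of a uniform vial are untouched at every b
  p0 <- st$protocol
  p0$noise_sigma <- 0
  clean <- simulate_dwi_series(lay, p0, default_adc_model(), 21, seed = 1)
  # separable kernel corner reach is sqrt(2)*4 px = 6.8 mm; stay beyond it
  deep <- outer((xc - v0$x_mm)^2, (xc - v0$y_mm)^2, `+`) < (v0$radius_mm - 7)^2
  for (lv in c("LOW", "MEDIUM", "HIGH")) {
    smc <- emulate_dl_reconstruction(clean, lv)
    for (k in c(1, 5)) {
      expect_equal(smc$data[, , 1, k][deep], clean$data[, , 1, k][deep],
                   tolerance = 1e-10)
    }
  }
  # and within 0.1% for the noisy high-SNR images
  for (lv in c("LOW", "MEDIUM", "HIGH")) {
    sm <- emulate_dl_reconstruction(st, lv)
    for (k in c(1, 2)) {
      m0 <- mean(st$data[, , , k][array(interior, dim = dim(st$data)[1:3])])
      m1 <- mean(sm$data[, , , k][array(interior, dim = dim(st$data)[1:3])])
      expect_lt(abs(m1 - m0) / m0, 0.001)
    }
  }

  expect_error(emulate_dl_reconstruction(st, "ULTRA"), "unknown reconstruction level")
})

test_that("Rician floor: noisy mean exceeds noiseless signal at b=2000 in water", {
  st <- small_noisy_stack(7)
  p <- st$protocol
  lay <- compact_layout(SMALL_FOV)
  v0 <- lay$vials[lay$vials$label == "PVP0_C", ]
  xc <- (seq_len(SMALL_MATRIX) - 0.5) * SMALL_PX
  interior <- outer((xc - v0$x_mm)^2, (xc - v0$y_mm)^2, `+`) < (v0$radius_mm - 4)^2
  expect_gt(sum(interior) * 5, 1e3)
  s_true <- p$s0 * exp(-2000 * st$ground_truth[["PVP0_C"]])
  noisy_mean <- mean(st$data[, , , 5][array(interior, dim = dim(st$data)[1:3])])
  expect_gte(noisy_mean, s_true)
})

test_that("simulate_study shares raw realizations across levels", {
  des <- default_study_design(
    n_repeats = 2L,
    sessions = data.frame(session = "S1", temperature_c = 21),
    base_seed = 5L)
  p <- default_protocol("fFOV", matrix = 32L, n_slices = 2L, pixel_mm = 3.6)
  lay <- compact_layout(32 * 3.6, ring_mm = 28, bath_radius_mm = 47)
  st <- simulate_study(des, "fFOV", protocol = p, layout = lay)
  expect_length(st, 2 * 4)
  # repeats differ
  expect_false(identical(st[["S1_r1_OFF"]]$data, st[["S1_r2_OFF"]]$data))
  # OFF and HIGH of one repeat come from the same raw realization:
  # smoothing the OFF stack reproduces the HIGH stack exactly
  resm <- emulate_dl_reconstruction(st[["S1_r1_OFF"]], "HIGH")
  expect_equal(resm$data, st[["S1_r1_HIGH"]]$data, tolerance = 1e-14)
  # full rerun is bit-identical
  st2 <- simulate_study(des, "fFOV", protocol = p, layout = lay)
  expect_identical(lapply(st, `[[`, "data"), lapply(st2, `[[`, "data"))
})

test_that("derive_seed is stable, distinct, and in integer range", {
  s <- outer(1:4, 1:6, Vectorize(function(i, j) derive_seed(123, i, j)))
  expect_equal(length(unique(as.vector(s))), 24)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(derive_seed(123, 2, 3), derive_seed(123, 2, 3))
})
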