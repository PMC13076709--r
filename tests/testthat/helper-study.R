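# Shared small-scale study fixtures, built in code at test time.

# Compact 5-vial ring layout used when the grid cannot hold the full
# 13-vial phantom at a clinically plausible pixel size: water plus the
# 20-50% PVP vials on one ring, full vial radius so VOIs stay interior.
compact_layout <- function(fov_mm, ring_mm = 28, bath_radius_mm = 47) {
  cx <- fov_mm / 2
  ang <- (0:4) * 2 * pi / 5
  v <- data.frame(
    label = c("PVP0_C", "PVP20_I", "PVP30_I", "PVP40_I", "PVP50_I"),
    pvp_fraction = c(0, 0.2, 0.3, 0.4, 0.5),
    ring = c("central", rep("inner", 4)),
    x_mm = cx + ring_mm * cos(ang),
    y_mm = cx + ring_mm * sin(ang),
    radius_mm = 16)
  build_phantom_layout("fFOV", config = list(
    fov_mm = fov_mm, vials = v, bath_radius_mm = bath_radius_mm))
}

# Tiny full-13-vial world on a coarse grid; fast enough for pipeline tests.
tiny_config <- function(sequences = "fFOV", seed = 11L, n_repeats = 2L,
                        sessions = data.frame(session = c("S1", "S2"),
                                              temperature_c = c(22.9, 20.8))) {
  default_config(
    sequences = sequences, seed = seed,
    protocol = list(matrix = 64L, n_slices = 3L, pixel_mm = 2.4),
    design = list(n_repeats = n_repeats, sessions = sessions))
}

# One small noisy stack over the compact layout (memoized per seed).
SMALL_PX <- 1.2
SMALL_MATRIX <- 96L
SMALL_FOV <- SMALL_PX * SMALL_MATRIX
local({
  cache <- new.env(parent = emptyenv())
  small_noisy_stack <<- function(seed = 7L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      p <- default_protocol("fFOV", matrix = SMALL_MATRIX, n_slices = 5L,
                            pixel_mm = SMALL_PX)
      cache[[key]] <- simulate_dwi_series(compact_layout(SMALL_FOV), p,
                                          default_adc_model(), 21, seed = seed)
    }
    cache[[key]]
  }
})
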