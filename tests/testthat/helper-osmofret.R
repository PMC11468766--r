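# Shared builders for the test suite. All synthetic data are generated in
# code under fixed seeds; no fixture files.

# Noiseless CLSM-mode calibration curve for the PEGylated microscopy sensor,
# sampled densely across its working range.
make_clsm_curve <- function() {
  spec <- builtin_spec("Lip-PEG10-DA-0.05")
  pts <- simulate_calibration(spec, seq(0.05, 1.3, by = 0.05))
  fit_curve(pts, pi_lo = 0.05, linear_window = c(0.05, 1.3))
}

# Deterministic grid of well-separated spot centers inside a frame.
grid_centers <- function(n, shape, spacing = 16, offset = 10) {
  per_row <- floor((shape[2] - 2 * offset) / spacing) + 1
  idx <- seq_len(n) - 1
  cbind(offset + (idx %/% per_row) * spacing,
        offset + (idx %% per_row) * spacing)
}

# Field + control pair rendered at one pressure; returns the recovered
# ROI-sum FRET ratio together with the intermediate objects.
run_roi_pipeline <- function(pressure, curve, seed, n_spots = 200,
                             shape = c(512, 512), pixel_size_um = 0.4,
                             roi_um = 150) {
  sc <- random_scene(n_spots, shape, pressure = pressure, seed = seed)
  fld <- synth_field(sc, curve, seed = seed + 1L,
                     pixel_size_um = pixel_size_um)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2),
                           background = sc$background),
                     seed = seed + 2L, pixel_size_um = pixel_size_um)
  thr <- noise_threshold(ctl$stack)
  mask <- segment(fld$stack, thr)
  list(ratio = roi_average_ratio(fld$stack, mask, roi_um),
       stack = fld$stack, mask = mask, truth = fld$truth, thresholds = thr)
}

# Time-lapse frame/background pair series at given per-frame pressures.
make_timelapse <- function(pressures, curve, shape = c(128, 128),
                           seed0 = 500) {
  centers <- grid_centers(16, shape, spacing = 24, offset = 16)
  frames <- list()
  bgs <- list()
  for (t in seq_along(pressures)) {
    sc <- scene(shape, centers, pressure = pressures[t], amplitude = 3000,
                background = 2)
    frames[[t]] <- synth_field(sc, curve, seed = seed0 + 2 * t,
                               pixel_size_um = 0.4,
                               time_index = t)$stack
    bgs[[t]] <- synth_field(scene(shape, matrix(numeric(0), 0, 2),
                                  background = 2),
                            seed = seed0 + 2 * t + 1, pixel_size_um = 0.4,
                            time_index = t)$stack
  }
  list(frames = frames, bgs = bgs)
}
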