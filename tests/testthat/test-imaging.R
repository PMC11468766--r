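test_that("zero-spot scenes render control frames; spots render as blobs", {
  shape <- c(96, 96)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                     seed = 1)
  expect_true(ctl$stack$is_control)
  expect_false(any(ctl$truth$support))
  n <- 12
  sc <- scene(shape, grid_centers(n, shape), ratio = 60, amplitude = 1000,
              background = 2)
  noiseless <- synth_field(sc, noise = list(poisson = FALSE, read_sd = 0),
                           seed = 1)
  # every spot leaves a bright peak in its own support window
  blobs <- 0
  for (i in seq_len(n)) {
    w <- noiseless$stack$donor[sc$centers[i, 1] + (-3:3),
                               sc$centers[i, 2] + (-3:3)]
    blobs <- blobs + (max(w) > 500)
  }
  expect_equal(blobs, n)
  expect_error(scene(shape, cbind(200, 50), pressure = 0.1), "inside the frame")
})

test_that("identical seeds give identical frames", {
  sc <- random_scene(20, c(80, 80), pressure = 0.3, seed = 5)
  a <- synth_field(sc, make_clsm_curve(), seed = 9)
  b <- synth_field(sc, make_clsm_curve(), seed = 9)
  expect_identical(a$stack$donor, b$stack$donor)
  expect_identical(a$stack$fret, b$stack$fret)
})

test_that("spot-integrated FRET/donor ratio is unbiased over seeds", {
  shape <- c(40, 40)
  sc <- scene(shape, cbind(20.5, 20.5), ratio = 65, amplitude = 2000,
              background = 0)
  ratios <- vapply(seq_len(200), function(k) {
    f <- synth_field(sc, seed = k)
    sup <- f$truth$support
    100 * sum(f$stack$fret[sup]) / sum(f$stack$donor[sup])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 65), 4 * stats::sd(ratios) / sqrt(200))
})

test_that("noise thresholds sit one count above the control maximum", {
  donor <- matrix(0L, 10, 10); donor[3, 7] <- 87L
  ctl <- channel_stack(donor, matrix(12L, 10, 10), matrix(5L, 10, 10),
                       is_control = TRUE)
  thr <- noise_threshold(ctl)
  expect_equal(unname(thr["donor"]), 88)
  expect_equal(unname(thr["fret"]), 13)
  zero <- channel_stack(matrix(0L, 4, 4), matrix(0L, 4, 4), matrix(0L, 4, 4),
                        is_control = TRUE)
  expect_equal(unname(noise_threshold(zero)["donor"]), 1)
  not_ctl <- channel_stack(donor, donor, donor)
  expect_error(noise_threshold(not_ctl), "control")
})

test_that("thresholds applied to their own control yield an empty mask, any seed", {
  for (k in c(2, 17, 403)) {
    ctl <- synth_field(scene(c(64, 64), matrix(numeric(0), 0, 2),
                             background = 5), seed = k)
    mask <- segment(ctl$stack, noise_threshold(ctl$stack))
    expect_equal(sum(mask), 0)
  }
})

test_that("segmentation keeps spot pixels and drops saturated ones", {
  shape <- c(96, 96)
  sc <- scene(shape, grid_centers(6, shape), ratio = 60, amplitude = 2500,
              background = 2)
  fld <- synth_field(sc, seed = 3)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                     seed = 4)
  thr <- noise_threshold(ctl$stack)
  mask <- segment(fld$stack, thr)
  expect_gt(sum(mask), 0)
  expect_true(all(fld$truth$support[mask]))
  # saturate one masked pixel in the fret channel: it must drop out
  px <- which(mask, arr.ind = TRUE)[1, ]
  stack2 <- fld$stack
  stack2$fret[px[1], px[2]] <- 2^stack2$bit_depth - 1
  mask2 <- segment(stack2, thr)
  expect_false(mask2[px[1], px[2]])
})

test_that("pixel ratios are exact on uniform frames and gain-invariant", {
  donor <- matrix(100, 8, 8); fret <- matrix(50, 8, 8)
  st <- channel_stack(donor, fret, fret)
  mask <- matrix(TRUE, 8, 8)
  rm1 <- ratio_map(st, mask)
  expect_true(all(rm1$values == 50))
  expect_true(all(rm1$status == "ok"))
  st2 <- channel_stack(2 * donor, 2 * fret, fret)
  expect_equal(ratio_map(st2, mask)$values, rm1$values)
})

test_that("masked-pixel mean tracks the scene ratio on a synthetic field", {
  shape <- c(128, 128)
  sc <- scene(shape, grid_centers(20, shape, spacing = 20), ratio = 70,
              amplitude = 3000, background = 2)
  fld <- synth_field(sc, seed = 8)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                     seed = 9)
  mask <- segment(fld$stack, noise_threshold(ctl$stack))
  rm <- ratio_map(fld$stack, mask)
  expect_lt(abs(mean(rm$values[mask]) - 70), 4)
})

test_that("ROI-sum ratio equals the donor-weighted mean of pixel ratios", {
  shape <- c(64, 64)
  sc <- scene(shape, grid_centers(8, shape, spacing = 14, offset = 12),
              ratio = 55, amplitude = 2000, background = 2)
  fld <- synth_field(sc, seed = 21, pixel_size_um = 1)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                     seed = 22, pixel_size_um = 1)
  mask <- segment(fld$stack, noise_threshold(ctl$stack))
  roi_um <- 64
  r_roi <- roi_average_ratio(fld$stack, mask, roi_um)
  rm <- ratio_map(fld$stack, mask)
  w <- fld$stack$donor[mask]
  expect_equal(r_roi, sum(w * rm$values[mask]) / sum(w), tolerance = 1e-12)
  # uniform frames: ROI-sum equals the pixelwise ratio
  uni <- channel_stack(matrix(200, 64, 64), matrix(90, 64, 64),
                       matrix(90, 64, 64), pixel_size_um = 1)
  expect_equal(roi_average_ratio(uni, matrix(TRUE, 64, 64), 30), 45)
  expect_error(roi_average_ratio(uni, matrix(FALSE, 64, 64), 30),
               "no sensor-containing pixel")
  expect_error(roi_average_ratio(uni, matrix(TRUE, 64, 64), 1000),
               "does not fit")
})

test_that("pressure maps round-trip constants and flag out-of-range pixels", {
  curve <- make_clsm_curve()
  vals <- matrix(predict(curve, 0.35), 6, 6)
  donor <- matrix(1000, 6, 6)
  fret <- matrix(round(donor * vals / 100), 6, 6)
  st <- channel_stack(donor, fret, fret)
  mask <- matrix(TRUE, 6, 6)
  pm <- pressure_map(ratio_map(st, mask), curve)
  expect_true(all(pm$status == "ok"))
  expect_equal(unique(as.vector(pm$values)), 0.35, tolerance = 2e-3)
  # ratio above the curve maximum
  hot <- channel_stack(donor, matrix(2000, 6, 6), fret)
  pm2 <- pressure_map(ratio_map(hot, mask), curve)
  expect_true(all(pm2$status == "above_range"))
  expect_true(all(pm2$values <= curve$pi_hi_model))
  # spectro curves are refused
  spectro <- fit_curve(simulate_calibration(builtin_spec("Lip-DA-0.05"),
                                            seq(0.05, 0.5, by = 0.05)),
                       pi_lo = 0.05)
  expect_error(pressure_map(ratio_map(st, mask), spectro), "CLSM")
})

test_that("a two-pressure field maps to two recoverable pressure regions", {
  curve <- make_clsm_curve()
  shape <- c(192, 192)
  low <- grid_centers(24, c(192, 90), spacing = 18, offset = 12)
  high <- grid_centers(24, c(192, 90), spacing = 18, offset = 12)
  high[, 2] <- high[, 2] + 96
  sc <- scene(shape, rbind(low, high),
              pressure = rep(c(0.05, 0.93), each = 24),
              amplitude = 3000, background = 2)
  fld <- synth_field(sc, curve, seed = 31)
  ctl <- synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                     seed = 32)
  mask <- segment(fld$stack, noise_threshold(ctl$stack))
  pm <- pressure_map(ratio_map(fld$stack, mask), curve)
  left <- pm$values[, 1:96][mask[, 1:96] & pm$status[, 1:96] == "ok"]
  right <- pm$values[, 97:192][mask[, 97:192] & pm$status[, 97:192] == "ok"]
  expect_lt(abs(stats::median(left) - 0.05), 0.1)
  expect_lt(abs(stats::median(right) - 0.93), 0.1)
})

test_that("end-to-end ROI pipeline recovers pressure within 0.05 MPa", {
  curve <- make_clsm_curve()
  for (p in c(0.1, 0.35, 0.7, 0.93, 1.1)) {
    for (k in 1:10) {
      out <- run_roi_pipeline(p, curve, seed = 1000 * k + round(100 * p),
                              n_spots = 60, shape = c(192, 192),
                              pixel_size_um = 0.4, roi_um = 70)
      inv <- invert(curve, out$ratio)
      expect_equal(inv$status, "in_range", info = sprintf("p=%g k=%d", p, k))
      expect_lt(abs(inv$pressure_MPa - p), 0.05)
    }
  }
})

test_that("stacks and maps survive TIFF round trips", {
  sc <- scene(c(48, 48), grid_centers(4, c(48, 48)), ratio = 60,
              amplitude = 1500, background = 2)
  fld <- synth_field(sc, seed = 40)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(fld$stack, path)
  back <- read_stack(path)
  expect_equal(back$donor, fld$stack$donor)
  expect_equal(back$fret, fld$stack$fret)
  expect_equal(back$bit_depth, fld$stack$bit_depth)
  expect_equal(back$pixel_size_um, fld$stack$pixel_size_um)
  ctl <- synth_field(scene(c(48, 48), matrix(numeric(0), 0, 2),
                           background = 2), seed = 41)
  mask <- segment(fld$stack, noise_threshold(ctl$stack))
  rm <- ratio_map(fld$stack, mask)
  prefix <- file.path(withr::local_tempdir(), "rmap")
  write_map(rm, prefix)
  expect_true(file.exists(paste0(prefix, ".tif")))
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(csv), sum(mask))
  expect_equal(sort(csv$value), sort(rm$values[mask]))
})


test_that("time-lapse monitoring detects a medium-exchange step within one frame", {
  curve <- make_clsm_curve()
  k <- 13
  pressures <- c(rep(0.35, k - 1), rep(0.7, 8))
  tl <- make_timelapse(pressures, curve)
  out <- timelapse_monitor(tl$frames, tl$bgs, curve, roi_um = 45)
  expect_equal(nrow(out$series), length(pressures))
  expect_true(all(out$series$status == "in_range"))
  expect_lt(max(abs(out$series$pressure_MPa[1:(k - 1)] - 0.35)), 0.05)
  expect_lte(abs(out$change_point - k), 1)
})

test_that("a constant series yields a flat trace and no change point", {
  curve <- make_clsm_curve()
  tl <- make_timelapse(rep(0.35, 12), curve, seed0 = 700)
  out <- timelapse_monitor(tl$frames, tl$bgs, curve, roi_um = 45)
  expect_true(is.na(out$change_point))
  expect_lt(stats::sd(out$series$pressure_MPa), 0.02)
  expect_equal(out$series$time_s, 21 * (0:11))
})

test_that("a background-only series reports no-sensor frames", {
  curve <- make_clsm_curve()
  shape <- c(64, 64)
  frames <- lapply(1:6, function(t)
    synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                seed = 900 + 2 * t, pixel_size_um = 0.4)$stack)
  bgs <- lapply(1:6, function(t)
    synth_field(scene(shape, matrix(numeric(0), 0, 2), background = 2),
                seed = 901 + 2 * t, pixel_size_um = 0.4)$stack)
  out <- timelapse_monitor(frames, bgs, curve, roi_um = 20)
  expect_true(all(out$series$status == "no_sensor"))
  expect_true(all(is.na(out$series$pressure_MPa)))
  # mismatched shapes are refused
  bad <- synth_field(scene(c(32, 32), matrix(numeric(0), 0, 2),
                           background = 2), seed = 950)$stack
  expect_error(timelapse_monitor(frames, c(bgs[-1], list(bad)), curve,
                                 roi_um = 20),
               "shape mismatch")
})
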