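#' @title Synthetic confocal fields
#' @name imaging_synth
#' @description Generates three-channel (donor / FRET / acceptor) confocal
#'   frames of sub-resolution liposome sensors: Gaussian point-spread blobs
#'   whose FRET/donor amplitude split follows a calibration curve at each
#'   spot's osmotic pressure, over a uniform background, with Poisson photon
#'   noise and Gaussian read noise.
NULL

#' Construct a three-channel image stack
#'
#' @param donor,fret,acceptor Equal-shape matrices of non-negative integer
#'   pixel counts. Donor and FRET are the two 458 nm-excitation channels
#'   entering the FRET ratio; the acceptor channel (561 nm excitation) is
#'   carried as metadata for completeness.
#' @param bit_depth Detector bit depth (8, 12 or 16); pixel values must not
#'   exceed `2^bit_depth - 1`.
#' @param pixel_size_um Pixel size, micrometers per pixel.
#' @param time_index Optional frame index in a time-lapse series.
#' @param is_control TRUE for a sensor-free control frame.
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(donor, fret, acceptor, bit_depth = 12,
                          pixel_size_um = 0.2, time_index = NA_integer_,
                          is_control = FALSE) {
  stopifnot(is.matrix(donor), is.matrix(fret), is.matrix(acceptor))
  if (!all(dim(donor) == dim(fret)) || !all(dim(donor) == dim(acceptor)))
    stop("channel shapes differ")
  if (!bit_depth %in% c(8, 12, 16)) stop("bit_depth must be 8, 12 or 16")
  full <- 2^bit_depth - 1
  for (ch in list(donor, fret, acceptor)) {
    if (any(ch < 0) || any(ch > full))
      stop("pixel values must lie in [0, 2^bit_depth - 1]")
  }
  structure(list(donor = donor, fret = fret, acceptor = acceptor,
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um,
                 time_index = time_index, is_control = isTRUE(is_control)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %d x %d px, %d-bit, %.2f um/px%s%s\n",
              nrow(x$donor), ncol(x$donor), x$bit_depth, x$pixel_size_um,
              if (x$is_control) " [control]" else "",
              if (!is.na(x$time_index)) sprintf(" t=%d", x$time_index) else ""))
  invisible(x)
}

full_scale <- function(stack) 2^stack$bit_depth - 1

#' Describe a synthetic scene of liposome spots
#'
#' Ground truth for a synthetic field: spot centers in continuous pixel
#' coordinates, the per-spot osmotic pressure (or directly a per-spot FRET
#' ratio), the donor-channel blob amplitude, the point-spread sigma and the
#' uniform background level.
#'
#' @param shape Frame shape, `c(nrow, ncol)` pixels.
#' @param centers n x 2 matrix of (row, col) continuous pixel coordinates
#'   (1-based); must lie inside the frame.
#' @param pressure Per-spot osmotic pressure, MPa (recycled); ignored when
#'   `ratio` is given.
#' @param ratio Optional per-spot FRET ratio, % (recycled).
#' @param amplitude Donor-channel peak amplitude per spot, counts (recycled).
#' @param psf_sigma_px Gaussian point-spread sigma, pixels.
#' @param background Uniform background level, counts.
#' @return Object of class `scene`.
#' @export
scene <- function(shape, centers, pressure = NULL, ratio = NULL,
                  amplitude = 3000, psf_sigma_px = 2, background = 2) {
  centers <- matrix(centers, ncol = 2)
  n <- nrow(centers)
  if (n > 0) {
    if (any(centers[, 1] < 1) || any(centers[, 1] > shape[1]) ||
        any(centers[, 2] < 1) || any(centers[, 2] > shape[2]))
      stop("spot centers must lie inside the frame")
  }
  if (is.null(pressure) && is.null(ratio) && n > 0)
    stop("each spot needs a pressure or a ratio")
  if (any(amplitude <= 0)) stop("amplitudes must be > 0")
  structure(list(shape = as.integer(shape), centers = centers,
                 pressure = if (is.null(pressure)) NULL else rep(pressure, length.out = n),
                 ratio = if (is.null(ratio)) NULL else rep(ratio, length.out = n),
                 amplitude = rep(amplitude, length.out = n),
                 psf_sigma_px = psf_sigma_px, background = background),
            class = "scene")
}

#' Random scene of uniformly placed spots
#'
#' @param n_spots Number of spots.
#' @param shape Frame shape, `c(nrow, ncol)`.
#' @param pressure Osmotic pressure for all spots, MPa.
#' @param seed Integer RNG seed (spot placement).
#' @param margin_px Keep-out margin from the frame edge, pixels.
#' @param ... Passed to [scene()].
#' @return A [scene()].
#' @export
random_scene <- function(n_spots, shape, pressure, seed = 1L,
                         margin_px = 8, ...) {
  set.seed(seed)
  ctr <- cbind(stats::runif(n_spots, 1 + margin_px, shape[1] - margin_px),
               stats::runif(n_spots, 1 + margin_px, shape[2] - margin_px))
  scene(shape, ctr, pressure = pressure, ...)
}

# add a Gaussian blob to img in-place-ish; window limited to +-4 sigma
add_blob <- function(img, row0, col0, amp, sigma) {
  w <- ceiling(4 * sigma)
  r <- max(1, floor(row0 - w)):min(nrow(img), ceiling(row0 + w))
  c <- max(1, floor(col0 - w)):min(ncol(img), ceiling(col0 + w))
  g <- exp(-outer((r - row0)^2, (c - col0)^2, "+") / (2 * sigma^2))
  img[r, c] <- img[r, c] + amp * g
  img
}

scene_spot_ratio <- function(sc, curve) {
  if (!is.null(sc$ratio)) return(sc$ratio)
  if (inherits(curve, "sensor_spec")) response_ratio(curve, sc$pressure)
  else if (inherits(curve, "calibration_curve")) predict(curve, sc$pressure)
  else stop("curve must be a sensor_spec or calibration_curve")
}

#' Render a synthetic three-channel confocal field
#'
#' Each spot contributes a Gaussian blob to the donor and FRET channels with
#' its amplitude split so that the expected FRET/donor ratio at the spot
#' equals the calibration ratio at the spot's pressure; the acceptor channel
#' is rendered proportional to the FRET channel signal. Poisson photon noise
#' and Gaussian read noise are applied, values are rounded and clipped to
#' the bit depth (clipped pixels are saturated and later excluded by
#' segmentation).
#'
#' @param sc A [scene()]; zero spots gives a control frame (background and
#'   noise only).
#' @param curve A `calibration_curve` (CLSM mode) or [sensor_spec()] mapping
#'   the spot pressures to FRET ratios; unused when the scene carries
#'   per-spot ratios.
#' @param noise List with elements `poisson` (logical) and `read_sd`
#'   (counts).
#' @param seed Integer RNG seed; identical seeds give identical frames.
#' @param bit_depth,pixel_size_um,is_control,time_index Stack metadata.
#' @param acceptor_gain Proportionality of the acceptor channel to the FRET
#'   channel signal.
#' @return List with elements `stack` (a [channel_stack()]) and `truth`
#'   (list: `ratio` matrix of ground-truth spot ratios over each spot's
#'   rendered footprint (4-sigma disk), NA elsewhere; `support` logical
#'   matrix of the same footprint; `spot_ratio` per-spot ratios).
#' @export
synth_field <- function(sc, curve = NULL,
                        noise = list(poisson = TRUE, read_sd = 3),
                        seed = 1L, bit_depth = 12, pixel_size_um = 0.2,
                        is_control = NULL, time_index = NA_integer_,
                        acceptor_gain = 0.9) {
  stopifnot(inherits(sc, "scene"))
  n <- nrow(sc$centers)
  shape <- sc$shape
  donor <- matrix(sc$background, shape[1], shape[2])
  fret <- matrix(sc$background, shape[1], shape[2])
  support <- matrix(FALSE, shape[1], shape[2])
  truth_ratio <- matrix(NA_real_, shape[1], shape[2])
  ratios <- if (n > 0) scene_spot_ratio(sc, curve) else numeric(0)
  for (i in seq_len(n)) {
    donor <- add_blob(donor, sc$centers[i, 1], sc$centers[i, 2],
                      sc$amplitude[i], sc$psf_sigma_px)
    fret <- add_blob(fret, sc$centers[i, 1], sc$centers[i, 2],
                     sc$amplitude[i] * ratios[i] / 100, sc$psf_sigma_px)
    w <- 4 * sc$psf_sigma_px # rendered footprint
    rr <- max(1, floor(sc$centers[i, 1] - w)):min(shape[1], ceiling(sc$centers[i, 1] + w))
    cc <- max(1, floor(sc$centers[i, 2] - w)):min(shape[2], ceiling(sc$centers[i, 2] + w))
    d2 <- outer((rr - sc$centers[i, 1])^2, (cc - sc$centers[i, 2])^2, "+")
    inside <- d2 <= w^2
    support[rr, cc][inside] <- TRUE
    truth_ratio[rr, cc][inside] <- ratios[i]
  }
  acceptor <- sc$background + acceptor_gain * (fret - sc$background)
  set.seed(seed)
  apply_noise <- function(expected) {
    x <- if (isTRUE(noise$poisson)) stats::rpois(length(expected), expected)
         else expected
    if (!is.null(noise$read_sd) && noise$read_sd > 0)
      x <- x + stats::rnorm(length(expected), 0, noise$read_sd)
    matrix(pmin(pmax(round(x), 0), 2^bit_depth - 1), nrow(expected))
  }
  stack <- channel_stack(apply_noise(donor), apply_noise(fret),
                         apply_noise(acceptor),
                         bit_depth = bit_depth, pixel_size_um = pixel_size_um,
                         time_index = time_index,
                         is_control = if (is.null(is_control)) n == 0 else is_control)
  list(stack = stack,
       truth = list(ratio = truth_ratio, support = support,
                    spot_ratio = ratios))
}
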