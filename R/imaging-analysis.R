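#' @title Confocal image analysis chain
#' @name imaging_analysis
#' @description Control-derived noise thresholds, segmentation of
#'   sensor-containing pixels, pixel-wise and ROI-sum FRET ratios, per-pixel
#'   osmotic pressure maps, and time-lapse monitoring with change-point
#'   detection.
NULL

#' Noise thresholds from a sensor-free control frame
#'
#' Per channel, the threshold is set just above the brightest control pixel:
#' maximum control value + 1 count, the smallest representable increment.
#' Applying the thresholds back to the control itself therefore yields an
#' empty mask for any noise realization.
#'
#' @param control A [channel_stack()] with `is_control = TRUE`.
#' @return Named numeric vector with elements `donor`, `fret`, `acceptor`.
#' @export
noise_threshold <- function(control) {
  stopifnot(inherits(control, "channel_stack"))
  if (!control$is_control)
    stop("thresholds must be derived from a sensor-free control frame")
  c(donor = max(control$donor) + 1,
    fret = max(control$fret) + 1,
    acceptor = max(control$acceptor) + 1)
}

#' Segment sensor-containing pixels
#'
#' A pixel belongs to the sensor mask iff both 458 nm-excitation channels
#' (donor and FRET — the two channels entering the ratio) are at or above
#' their control-derived thresholds and neither is saturated (at the
#' full-scale value of the bit depth).
#'
#' @param stack A [channel_stack()].
#' @param thresholds Output of [noise_threshold()] on the matching control.
#' @return Logical matrix mask.
#' @export
segment <- function(stack, thresholds) {
  stopifnot(inherits(stack, "channel_stack"))
  if (!all(c("donor", "fret") %in% names(thresholds)))
    stop("thresholds need named elements donor and fret")
  full <- full_scale(stack)
  stack$donor >= thresholds[["donor"]] & stack$fret >= thresholds[["fret"]] &
    stack$donor < full & stack$fret < full
}

#' Pixel-wise FRET ratio map
#'
#' R = 100 * F_FRET / F_donor at each masked pixel; unmasked pixels are
#' excluded (NA value, status `excluded`).
#'
#' @param stack A [channel_stack()].
#' @param mask Logical mask from [segment()] on the same stack.
#' @return Object of class `ratio_map`: list with `values` (matrix, %),
#'   `mask`, `status` (character matrix `ok`/`excluded`), `pixel_size_um`.
#' @export
ratio_map <- function(stack, mask) {
  stopifnot(inherits(stack, "channel_stack"), is.logical(mask),
            all(dim(mask) == dim(stack$donor)))
  stopifnot(all(stack$donor[mask] > 0)) # guaranteed by threshold >= 1
  values <- matrix(NA_real_, nrow(mask), ncol(mask))
  values[mask] <- 100 * stack$fret[mask] / stack$donor[mask]
  status <- matrix("excluded", nrow(mask), ncol(mask))
  status[mask] <- "ok"
  structure(list(values = values, mask = mask, status = status,
                 pixel_size_um = stack$pixel_size_um),
            class = "ratio_map")
}

roi_bounds <- function(shape, pixel_size_um, roi_um) {
  side <- floor(roi_um / pixel_size_um)
  if (side > shape[1] || side > shape[2])
    stop(sprintf("ROI of %g um (%d px) does not fit a %d x %d frame",
                 roi_um, side, shape[1], shape[2]))
  r0 <- floor((shape[1] - side) / 2) + 1L
  c0 <- floor((shape[2] - side) / 2) + 1L
  list(rows = r0:(r0 + side - 1L), cols = c0:(c0 + side - 1L))
}

#' ROI-sum FRET ratio
#'
#' The FRET ratio of a centered square region of interest, computed from
#' summed channel intensities over the masked (sensor-containing) pixels:
#' R = 100 * sum(F_FRET) / sum(F_donor). Algebraically this equals the
#' donor-intensity-weighted mean of the per-pixel ratios.
#'
#' @param stack A [channel_stack()].
#' @param mask Logical mask from [segment()].
#' @param roi_um Side of the centered square ROI, micrometers (converted to
#'   pixels via the stack's pixel size with floor rounding).
#' @return FRET ratio in %.
#' @export
roi_average_ratio <- function(stack, mask, roi_um = 150) {
  stopifnot(inherits(stack, "channel_stack"))
  b <- roi_bounds(dim(stack$donor), stack$pixel_size_um, roi_um)
  m <- mask[b$rows, b$cols]
  if (!any(m)) stop("no sensor-containing pixel inside the ROI")
  100 * sum(stack$fret[b$rows, b$cols][m]) /
    sum(stack$donor[b$rows, b$cols][m])
}

#' Per-pixel osmotic pressure map
#'
#' Inverts the CLSM-mode calibration curve at every masked pixel of a ratio
#' map. Out-of-range ratios are clamped to the corresponding sensing-range
#' endpoint and flagged; excluded pixels stay excluded.
#'
#' @param rmap A [ratio_map()].
#' @param curve A `calibration_curve` with instrument tag `"clsm"`.
#' @return Object of class `pressure_map`: list with `values` (matrix,
#'   MPa), `mask`, `status` (`ok`, `below_range`, `above_range`,
#'   `excluded`).
#' @export
pressure_map <- function(rmap, curve) {
  stopifnot(inherits(rmap, "ratio_map"), inherits(curve, "calibration_curve"))
  if (curve$instrument != "clsm")
    stop("pressure mapping requires a CLSM-mode calibration curve; ",
         "spectrofluorometer ratios are on a different scale")
  values <- matrix(NA_real_, nrow(rmap$values), ncol(rmap$values))
  status <- matrix("excluded", nrow(rmap$values), ncol(rmap$values))
  idx <- which(rmap$mask)
  if (length(idx) > 0) {
    inv <- invert(curve, rmap$values[idx])
    values[idx] <- inv$pressure_MPa
    status[idx] <- ifelse(inv$status == "in_range", "ok", inv$status)
  }
  structure(list(values = values, mask = rmap$mask, status = status,
                 pixel_size_um = rmap$pixel_size_um),
            class = "pressure_map")
}

#' Time-lapse osmotic pressure monitoring
#'
#' Reproduces the medium-exchange monitoring protocol: for every frame the
#' matching cell-only background frame is subtracted, sensor pixels are
#' segmented with thresholds derived from the background frame (treated as
#' the noise control), the ROI-sum FRET ratio is computed and inverted to a
#' mean osmotic pressure. A change point is reported at the first frame
#' whose pressure exceeds the running pre-exchange median by more than 3
#' median absolute deviations (MAD, normal-consistent scaling).
#'
#' @param stacks Time-ordered list of [channel_stack()]s (sensors + medium
#'   + cells).
#' @param background_stacks Matching list of cell-only frames (same shapes).
#' @param curve CLSM-mode `calibration_curve`.
#' @param roi_um ROI side, micrometers.
#' @param time_interval_s Acquisition interval, seconds (default 21 s).
#' @param min_baseline Minimum number of leading frames used as the
#'   pre-exchange baseline before change-point testing starts.
#' @return List with `series` (data.frame: `frame`, `time_s`, `ratio_pct`,
#'   `pressure_MPa`, `status`, `n_pixels`) and `change_point` (frame index
#'   or NA).
#' @export
timelapse_monitor <- function(stacks, background_stacks, curve, roi_um = 150,
                              time_interval_s = 21, min_baseline = 5) {
  stopifnot(length(stacks) == length(background_stacks), length(stacks) >= 1)
  n <- length(stacks)
  ratio <- pressure <- rep(NA_real_, n)
  status <- character(n)
  npix <- integer(n)
  for (t in seq_len(n)) {
    fr <- stacks[[t]]
    bg <- background_stacks[[t]]
    stopifnot(inherits(fr, "channel_stack"), inherits(bg, "channel_stack"))
    if (!all(dim(fr$donor) == dim(bg$donor)))
      stop(sprintf("frame %d: background shape mismatch", t))
    sub <- channel_stack(pmax(fr$donor - bg$donor, 0),
                         pmax(fr$fret - bg$fret, 0),
                         pmax(fr$acceptor - bg$acceptor, 0),
                         bit_depth = fr$bit_depth,
                         pixel_size_um = fr$pixel_size_um,
                         time_index = fr$time_index)
    ctrl <- channel_stack(bg$donor, bg$fret, bg$acceptor,
                          bit_depth = bg$bit_depth,
                          pixel_size_um = bg$pixel_size_um,
                          is_control = TRUE)
    mask <- segment(sub, noise_threshold(ctrl))
    b <- roi_bounds(dim(sub$donor), sub$pixel_size_um, roi_um)
    npix[t] <- sum(mask[b$rows, b$cols])
    if (npix[t] == 0) {
      status[t] <- "no_sensor"
      next
    }
    r <- roi_average_ratio(sub, mask, roi_um)
    inv <- invert(curve, r)
    ratio[t] <- r
    pressure[t] <- inv$pressure_MPa
    status[t] <- inv$status
  }
  change_point <- NA_integer_
  ok <- which(!is.na(pressure))
  for (t in seq_len(n)) {
    base <- ok[ok < t]
    if (length(base) < min_baseline || is.na(pressure[t])) next
    med <- stats::median(pressure[base])
    mad <- stats::mad(pressure[base])
    if (pressure[t] > med + max(3 * mad, 1e-9)) {
      change_point <- t
      break
    }
  }
  list(series = data.frame(frame = seq_len(n),
                           time_s = (seq_len(n) - 1) * time_interval_s,
                           ratio_pct = ratio, pressure_MPa = pressure,
                           status = status, n_pixels = npix),
       change_point = change_point)
}
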