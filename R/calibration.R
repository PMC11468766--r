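#' @title Calibration curves: fitting, sensing range, inversion
#' @name calibration
#' @description Builds the monotone R-Pi calibration curve from (pressure,
#'   ratio) measurements, estimates the initial ratio, sensitivity slope and
#'   sensing range, and inverts FRET ratios back to osmotic pressures.
NULL

pool_means <- function(points) {
  agg <- stats::aggregate(ratio_pct ~ pressure_MPa, data = points, FUN = mean)
  agg[order(agg$pressure_MPa), ]
}

as_points <- function(points) {
  stopifnot(is.data.frame(points))
  if (!all(c("pressure_MPa", "ratio_pct") %in% names(points)))
    stop("points need columns pressure_MPa and ratio_pct")
  if (any(points$pressure_MPa < 0)) stop("pressures must be >= 0")
  points
}

#' Fit a monotone calibration curve
#'
#' Replicates are pooled to per-pressure means; isotonic regression enforces
#' the monotone response asserted by the sensor physics (no functional form
#' is imposed); a shape-preserving monotone cubic interpolant (Hyman
#' filtering) through the isotonic values yields a smooth model that
#' reproduces noiseless monotone input exactly at the nodes.
#'
#' @param points data.frame with columns `pressure_MPa`, `ratio_pct` and
#'   optionally `replicate`, `instrument`; at least 3 distinct pressures.
#' @param pi_lo Lower bound of the sensing range (the sensor's intrinsic
#'   pressure), MPa. `R0_hat` is the fitted value there.
#' @param instrument Calibration modality tag (`"spectro"` or `"clsm"`);
#'   taken from the points when they carry an `instrument` column.
#' @param slope_floor_frac Fraction of the initial slope below which the
#'   response counts as saturated (defines the sensing-range upper bound).
#' @param linear_window Pressure window (length-2, MPa) for the sensitivity
#'   estimate `S_hat`; defaults to the full fitted domain, appropriate for
#'   sensors that are linear throughout.
#' @return Object of class `calibration_curve` with elements `points`,
#'   `means`, `model` (vectorized function of pressure), `R0_hat`, `S_hat`,
#'   `range_lo`, `range_hi` (`Inf` when the response never saturates within
#'   the fitted domain), `instrument`.
#' @export
fit_curve <- function(points, pi_lo = NULL, instrument = NULL,
                      slope_floor_frac = 0.1, linear_window = NULL) {
  points <- as_points(points)
  if (is.null(instrument)) {
    instrument <- if ("instrument" %in% names(points)) {
      u <- unique(points$instrument)
      if (length(u) != 1) stop("points mix calibration instruments")
      u
    } else "spectro"
  }
  instrument <- match.arg(instrument, c("spectro", "clsm"))
  means <- pool_means(points)
  if (nrow(means) < 3) stop("need at least 3 distinct pressures to calibrate")
  if (is.null(pi_lo)) pi_lo <- min(means$pressure_MPa)

  iso <- stats::isoreg(means$pressure_MPa, means$ratio_pct)
  yfit <- if (is.null(iso$ord)) iso$yf else iso$yf[order(iso$ord)]
  if (length(unique(yfit)) == 1) {
    warning("degenerate calibration: all fitted ratios equal; flat model")
    flat <- yfit[1]
    model <- function(pi) rep(flat, length(pi))
  } else {
    spline <- stats::splinefun(means$pressure_MPa, yfit, method = "hyman")
    x_min <- min(means$pressure_MPa)
    x_max <- max(means$pressure_MPa)
    model <- function(pi) spline(pmin(pmax(pi, x_min), x_max))
  }

  curve <- structure(
    list(points = points, means = means, iso_values = yfit, model = model,
         range_lo = max(pi_lo, min(means$pressure_MPa)),
         pi_hi_model = max(means$pressure_MPa),
         slope_floor_frac = slope_floor_frac, instrument = instrument),
    class = "calibration_curve")
  curve$R0_hat <- model(curve$range_lo)
  if (is.null(linear_window))
    linear_window <- c(curve$range_lo, curve$pi_hi_model)
  curve$S_hat <- linear_slope(points, linear_window)
  rng <- sensing_range(curve)
  curve$range_hi <- rng[2]
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  hi <- if (is.finite(x$range_hi)) sprintf("%.3f", x$range_hi) else "open"
  cat(sprintf(
    "<calibration_curve> %s  R0 = %.1f%%  S = %.1f %%/MPa  range [%.3f, %s] MPa  (%d pressures)\n",
    x$instrument, x$R0_hat, x$S_hat, x$range_lo, hi, nrow(x$means)))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param pressure Pressures, MPa.
#' @param ... Unused.
#' @return FRET ratio in % at each pressure.
#' @export
predict.calibration_curve <- function(object, pressure, ...) {
  object$model(pressure)
}

#' Ordinary least-squares slope and intercept in a pressure window
#'
#' @param points data.frame with `pressure_MPa`, `ratio_pct`.
#' @param window Length-2 pressure window, MPa (closed interval).
#' @return List with `slope` (%/MPa) and `intercept` (% at zero pressure).
#' @export
linear_fit <- function(points, window) {
  points <- as_points(points)
  stopifnot(length(window) == 2)
  sel <- points$pressure_MPa >= window[1] & points$pressure_MPa <= window[2]
  sub <- points[sel, ]
  if (length(unique(sub$pressure_MPa)) < 2)
    stop("need at least 2 distinct pressures inside the window")
  fit <- stats::lm(ratio_pct ~ pressure_MPa, data = sub)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Sensitivity slope in a pressure window
#'
#' The initial slope of the R-Pi curve is the sensor's sensitivity; it is
#' estimated by ordinary least squares restricted to the stated window.
#'
#' @inheritParams linear_fit
#' @return Slope in %/MPa.
#' @export
linear_slope <- function(points, window) {
  linear_fit(points, window)$slope
}

#' Sensing range of a fitted calibration curve
#'
#' The sensing range starts at the sensor's intrinsic osmotic pressure
#' (`range_lo`) and ends where the local slope of the fitted model falls
#' below `slope_floor_frac` times the initial slope, scanned on a 1 mPa
#' grid; it is open (upper bound `Inf`) when the slope never drops that far
#' within the fitted domain.
#'
#' @param curve A `calibration_curve`.
#' @return Numeric length-2 vector `c(lower, upper)`, MPa; `upper = Inf`
#'   when the range is open.
#' @export
sensing_range <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  lo <- curve$range_lo
  hi <- curve$pi_hi_model
  if (hi - lo < 2e-3) return(c(lo, Inf))
  grid <- seq(lo, hi, by = 1e-3)
  y <- curve$model(grid)
  sl <- diff(y) / diff(grid)
  if (sl[1] <= 0) return(c(lo, Inf))
  below <- which(sl < curve$slope_floor_frac * sl[1])
  if (length(below) == 0) return(c(lo, Inf))
  c(lo, grid[below[1]])
}

#' Invert FRET ratios to osmotic pressures
#'
#' Monotone inversion of the fitted model by vectorized bisection to 1e-6
#' MPa. A ratio landing on a flat isotonic step is resolved to the midpoint
#' of the step's pressure interval (unbiased under symmetric noise), with
#' the step width reported. Ratios outside the curve's range are clamped to
#' the nearest endpoint and flagged.
#'
#' @param curve A `calibration_curve`.
#' @param ratio FRET ratios, % (vectorized).
#' @param instrument Modality of the data being inverted; must match the
#'   curve's instrument tag (spectrofluorometer and confocal ratios are on
#'   systematically different scales and must never be mixed).
#' @return data.frame with columns `pressure_MPa`, `status` (one of
#'   `in_range`, `below_range`, `above_range`) and `ambiguous_width_MPa`.
#' @export
invert <- function(curve, ratio, instrument = curve$instrument) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!identical(instrument, curve$instrument))
    stop(sprintf(
      "calibration instrument mismatch: curve is '%s', data are '%s'",
      curve$instrument, instrument))
  lo <- curve$range_lo
  hi <- if (is.finite(curve$range_hi)) curve$range_hi else curve$pi_hi_model
  r_lo <- curve$model(lo)
  r_hi <- curve$model(hi)
  n <- length(ratio)
  status <- rep("in_range", n)
  status[ratio < r_lo] <- "below_range"
  status[ratio > r_hi] <- "above_range"
  pressure <- rep(NA_real_, n)
  width <- rep(0, n)
  pressure[status == "below_range"] <- lo
  pressure[status == "above_range"] <- hi
  inr <- status == "in_range"
  if (any(inr)) {
    r <- ratio[inr]
    # leftmost pressure with model >= r
    a1 <- rep(lo, length(r)); b1 <- rep(hi, length(r))
    # rightmost pressure with model <= r
    a2 <- rep(lo, length(r)); b2 <- rep(hi, length(r))
    for (k in seq_len(31)) {
      m1 <- (a1 + b1) / 2
      up <- curve$model(m1) >= r
      b1[up] <- m1[up]; a1[!up] <- m1[!up]
      m2 <- (a2 + b2) / 2
      dn <- curve$model(m2) <= r
      a2[dn] <- m2[dn]; b2[!dn] <- m2[!dn]
    }
    pressure[inr] <- (b1 + a2) / 2
    width[inr] <- pmax(0, a2 - b1)
  }
  data.frame(pressure_MPa = pressure, status = status,
             ambiguous_width_MPa = width)
}

#' Write calibration points to CSV
#'
#' Columns `sensor`, `instrument`, `pressure_MPa`, `ratio_pct`, `replicate`.
#'
#' @param points Calibration points data.frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_calibration_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Read calibration points from CSV
#'
#' @param path CSV written by [write_calibration_csv()].
#' @return data.frame of calibration points.
#' @export
read_calibration_csv <- function(path) {
  as_points(utils::read.csv(path))
}

#' Export a fitted curve as JSON
#'
#' Stores the interpolation nodes (pooled pressures and isotonic ratios) and
#' metadata; [read_curve_json()] rebuilds the identical model.
#'
#' @param curve A `calibration_curve`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(list(
    nodes = data.frame(pressure_MPa = curve$means$pressure_MPa,
                       ratio_pct = curve$iso_values),
    range_lo = curve$range_lo,
    slope_floor_frac = curve$slope_floor_frac,
    instrument = curve$instrument,
    R0_hat = curve$R0_hat, S_hat = curve$S_hat,
    range_hi = if (is.finite(curve$range_hi)) curve$range_hi else "open"
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild a fitted curve from JSON
#'
#' @param path JSON written by [write_curve_json()].
#' @return A `calibration_curve`.
#' @export
read_curve_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- data.frame(pressure_MPa = obj$nodes$pressure_MPa,
                    ratio_pct = obj$nodes$ratio_pct,
                    instrument = obj$instrument)
  fit_curve(pts, pi_lo = obj$range_lo,
            slope_floor_frac = obj$slope_floor_frac)
}
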