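#' @title Sensor forward model
#' @name sensor_forward
#' @description Phenomenological forward model of the liposome sensor FRET
#'   ratio R as a function of external osmotic pressure, plus the built-in
#'   library of sensor formulations and a seeded calibration-curve simulator.
NULL

#' Construct a sensor specification
#'
#' A sensor is described by its intrinsic (intraliposomal) osmotic pressure
#' `pi0`, the FRET ratio `R0` at that pressure, and a piecewise response:
#' one or more linear segments delimited by `breaks`, followed (when the last
#' break is finite) by an exponential approach to saturation with decay scale
#' `lam` that is C1-continuous at the last break. Below `pi0` the sensor is
#' osmotically turgid and the model returns a flat `R0` (the regime in which
#' real vesicles may swell and lose integrity; flagged, not modeled).
#'
#' @param name Sensor name, e.g. "Lip-DA-0.05".
#' @param pi0 Intrinsic osmotic pressure, MPa (lower bound of sensing range).
#' @param R0 FRET ratio at `pi0`, %.
#' @param slopes Slope of each linear segment, %/MPa (length m >= 1).
#' @param breaks Segment boundaries, MPa, length m + 1, strictly increasing,
#'   starting at `pi0`; the last element may be `Inf` for a sensor that stays
#'   linear over the whole modeled domain.
#' @param lam Saturation decay scale, MPa (> 0); ignored when the last break
#'   is infinite.
#' @param salt_in Intraliposomal NaCl load, % mass fraction (metadata).
#' @param dye_conc_uM Dye loading, micromolar (metadata).
#' @param instrument Calibration modality the parameterization refers to:
#'   `"spectro"` (spectrofluorometer F562/F520) or `"clsm"` (confocal
#'   F_FRET/F_donor). Ratios from the two modalities are systematically
#'   different and are never mixed downstream.
#' @param pi_max Upper bound of the modeled pressure domain, MPa.
#' @param diameter_nm,zeta_mV Optional descriptive metadata.
#' @return Object of class `sensor_spec`.
#' @export
sensor_spec <- function(name, pi0, R0, slopes, breaks, lam = NA_real_,
                        salt_in = NA_real_, dye_conc_uM = NA_real_,
                        instrument = "spectro", pi_max = 1.3,
                        diameter_nm = NA_real_, zeta_mV = NA_real_) {
  stopifnot(length(breaks) == length(slopes) + 1L,
            all(diff(breaks) > 0), breaks[1] == pi0)
  if (pi0 < 0) stop("pi0 must be >= 0")
  if (R0 <= 0) stop("R0 must be > 0")
  if (any(slopes < 0)) stop("slopes must be >= 0")
  if (is.finite(breaks[length(breaks)]) && (is.na(lam) || lam <= 0))
    stop("a finite last break requires a positive saturation scale lam")
  instrument <- match.arg(instrument, c("spectro", "clsm"))
  structure(list(name = name, pi0 = pi0, R0 = R0, slopes = slopes,
                 breaks = breaks, lam = lam, salt_in = salt_in,
                 dye_conc_uM = dye_conc_uM, instrument = instrument,
                 pi_max = pi_max, diameter_nm = diameter_nm,
                 zeta_mV = zeta_mV),
            class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  rng <- sensor_range_label(x)
  cat(sprintf("<sensor_spec> %s  R0 = %.1f%%  S = %.1f %%/MPa  range %s (%s)\n",
              x$name, x$R0, x$slopes[1], rng, x$instrument))
  invisible(x)
}

sensor_range_label <- function(spec) {
  last <- spec$breaks[length(spec$breaks)]
  if (is.finite(last)) sprintf("%.2f-", spec$pi0) else sprintf("%.2f- (open)", spec$pi0)
}

#' Forward FRET ratio of a sensor at given pressure
#'
#' Evaluates the piecewise response: flat `R0` below `pi0`; linear segments
#' between `breaks`; beyond a finite last break, `R_knee + S_last * lam *
#' (1 - exp(-(pi - knee)/lam))`, which matches the last linear slope at the
#' knee (C1) and saturates at `R_knee + S_last * lam`. Monotone
#' non-decreasing in `pi` for every valid spec.
#'
#' @param spec A [sensor_spec()].
#' @param pi External osmotic pressure, MPa (vectorized, >= 0).
#' @return FRET ratio in %.
#' @export
response_ratio <- function(spec, pi) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (any(pi < 0)) stop("pressure must be >= 0")
  r <- rep(spec$R0, length(pi))
  b <- spec$breaks
  m <- length(spec$slopes)
  for (j in seq_len(m)) {
    seg <- pmin(pmax(pi, b[j]), b[j + 1]) - b[j]
    r <- r + spec$slopes[j] * seg
  }
  knee <- b[m + 1]
  if (is.finite(knee)) {
    over <- pi > knee
    if (any(over)) {
      s <- spec$slopes[m]
      r[over] <- r[over] +
        s * spec$lam * (1 - exp(-(pi[over] - knee) / spec$lam))
    }
  }
  r
}

# Default saturation scale: with a 10% slope floor, the detected sensing
# range closes at knee + lam*log(10); lam is chosen so that equals the
# printed upper bound.
lam_for_upper <- function(knee, upper) (upper - knee) / log(10)

#' Built-in sensor library
#'
#' The salt-loaded POPC liposome formulations (Lip-DA-x, x = intraliposomal
#' NaCl % mass fraction) with initial ratio, linear-range slope and sensing
#' range as characterized by spectrofluorometry; the crosslinked cLip-DA-0
#' with its two-segment linear response; and the PEGylated Lip-PEG10-DA-0.05
#' in confocal (CLSM) mode, anchored at R = 43% at 0.05 MPa and R = 80% at
#' 0.93 MPa. Where the upper sensing bound is open-ended the response is
#' modeled linear across the whole domain; where it is printed, the
#' saturation knee sits at the stated end of the linear range (0.2 MPa for
#' Lip-DA-0) or at 2/3 of the upper bound, with the decay scale set so a 10%
#' slope floor reproduces the printed upper bound.
#'
#' @return Named list of [sensor_spec()] objects.
#' @export
builtin_specs <- function() {
  specs <- list(
    sensor_spec("Lip-DA-0", pi0 = 0, R0 = 125.3, slopes = 374.4,
                breaks = c(0, 0.2), lam = lam_for_upper(0.2, 0.3),
                salt_in = 0, dye_conc_uM = 50,
                diameter_nm = 1031, zeta_mV = -25.1),
    sensor_spec("Lip-DA-0.05", pi0 = 0.05, R0 = 97.3, slopes = 138.7,
                breaks = c(0.05, 0.85 * 2 / 3),
                lam = lam_for_upper(0.85 * 2 / 3, 0.85),
                salt_in = 0.05, dye_conc_uM = 50,
                diameter_nm = 1052, zeta_mV = -4.9),
    sensor_spec("Lip-DA-0.1", pi0 = 0.08, R0 = 86.6, slopes = 106.2,
                breaks = c(0.08, 0.8), lam = lam_for_upper(0.8, 1.2),
                salt_in = 0.1, dye_conc_uM = 50,
                diameter_nm = 1074, zeta_mV = -2.4),
    sensor_spec("Lip-DA-0.2", pi0 = 0.16, R0 = 64.9, slopes = 71.2,
                breaks = c(0.16, Inf), salt_in = 0.2, dye_conc_uM = 50,
                diameter_nm = 1045, zeta_mV = -2.2),
    sensor_spec("Lip-DA-0.45", pi0 = 0.35, R0 = 62.0, slopes = 25.7,
                breaks = c(0.35, Inf), salt_in = 0.45, dye_conc_uM = 50,
                diameter_nm = 1079, zeta_mV = -1.9),
    sensor_spec("Lip-DA-0.9", pi0 = 0.70, R0 = 60.2, slopes = 13.2,
                breaks = c(0.70, Inf), salt_in = 0.9, dye_conc_uM = 50,
                diameter_nm = 1108, zeta_mV = -1.1),
    # Crosslinked liposomes: two linear segments (150 then 60 %/MPa,
    # breakpoint 0.15 MPa), saturation setting in around 0.3 MPa. The
    # initial ratio is not tabulated; 100% is a nominal placeholder that no
    # slope or pressure anchor depends on.
    sensor_spec("cLip-DA-0", pi0 = 0, R0 = 100, slopes = c(150, 60),
                breaks = c(0, 0.15, 0.3), lam = 0.05,
                salt_in = 0, dye_conc_uM = 25),
    # Microscopy-mode PEGylated sensor: monotone (linear) interpolation
    # between the two CLSM calibration anchors.
    sensor_spec("Lip-PEG10-DA-0.05", pi0 = 0.05, R0 = 43,
                slopes = (80 - 43) / (0.93 - 0.05),
                breaks = c(0.05, Inf), salt_in = 0.05, dye_conc_uM = 75,
                instrument = "clsm")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Look up a built-in sensor by name
#'
#' @param name Sensor name as in [builtin_specs()].
#' @return A [sensor_spec()].
#' @export
builtin_spec <- function(name) {
  specs <- builtin_specs()
  if (!name %in% names(specs))
    stop(sprintf("unknown sensor '%s'; available: %s", name,
                 paste(names(specs), collapse = ", ")))
  specs[[name]]
}

#' Mechanistic intraliposomal dye-concentration factor
#'
#' In the deflation regime the internal osmotic pressure equilibrates with
#' the external one; conservation of entrapped solute (c * V constant) with
#' pressure proportional to concentration gives a dye-concentration increase
#' factor of `pi_ext / pi0`, floored at 1 in the turgid regime.
#'
#' @param pi0 Intraliposomal initial osmotic pressure, MPa (> 0).
#' @param pi_ext External osmotic pressure, MPa (vectorized).
#' @return Dimensionless concentration factor >= 1.
#' @export
mechanistic_dye_factor <- function(pi0, pi_ext) {
  if (pi0 <= 0)
    stop("mechanistic mode undefined for pi0 = 0 (pure-water load); use the empirical model")
  pmax(1, pi_ext / pi0)
}

SCREENING_ANCHORS <- data.frame(
  salt = c(0, 0.05, 0.1, 0.2, 0.45, 0.9),
  R0   = c(125.3, 97.3, 86.6, 64.9, 62.0, 60.2))

#' Initial FRET ratio vs intraliposomal salt (ion screening)
#'
#' Intraliposomal NaCl screens the electrostatic attraction between the
#' oppositely charged donor and acceptor dyes, increasing their average
#' separation and lowering the initial FRET ratio. Monotone non-increasing
#' shape-preserving interpolation through the measured formulation anchors,
#' exact at the anchors.
#'
#' @param salt_in Intraliposomal NaCl load, % mass fraction, in `[0, 0.9]`.
#' @return Initial FRET ratio R0 in %.
#' @export
screening_R0 <- function(salt_in) {
  if (any(salt_in < 0 | salt_in > 0.9))
    stop("salt_in outside the characterized range [0, 0.9]%; refusing to extrapolate")
  # decreasing data; hyman interpolation requires monotone increasing input
  f <- stats::splinefun(SCREENING_ANCHORS$salt, -SCREENING_ANCHORS$R0,
                        method = "hyman")
  -f(salt_in)
}

#' Simulate a calibration measurement series
#'
#' Draws replicate FRET-ratio readings at each pressure from the noiseless
#' forward model plus Gaussian noise with standard deviation `sigma`
#' (a ratio of two high-count intensities is well approximated as Gaussian).
#' Fully reproducible for a given seed.
#'
#' @param spec A [sensor_spec()].
#' @param pressures Pressures to measure at, MPa (non-empty).
#' @param sigma Noise standard deviation on the ratio, % (>= 0).
#' @param reps Replicates per pressure (>= 1).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `sensor`, `instrument`, `pressure_MPa`,
#'   `ratio_pct`, `replicate`.
#' @export
simulate_calibration <- function(spec, pressures, sigma = 0, reps = 1L,
                                 seed = 1L) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (length(pressures) == 0) stop("pressure list must be non-empty")
  if (sigma < 0) stop("sigma must be >= 0")
  if (reps < 1) stop("reps must be >= 1")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(reps), pressure_MPa = pressures,
                      KEEP.OUT.ATTRS = FALSE)
  truth <- response_ratio(spec, grid$pressure_MPa)
  noise <- if (sigma > 0) stats::rnorm(nrow(grid), 0, sigma) else 0
  data.frame(sensor = spec$name, instrument = spec$instrument,
             pressure_MPa = grid$pressure_MPa,
             ratio_pct = truth + noise,
             replicate = grid$replicate)
}

#' Export the sensor library as JSON
#'
#' @param path File path to write.
#' @param specs List of [sensor_spec()]s (default the built-in library).
#' @return `path`, invisibly.
#' @export
write_sensor_library <- function(path, specs = builtin_specs()) {
  recs <- lapply(specs, function(s) unclass(s))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a sensor library from JSON
#'
#' @param path File written by [write_sensor_library()].
#' @return Named list of [sensor_spec()]s.
#' @export
read_sensor_library <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  # jsonlite stores NA/Inf as the strings "NA"/"Inf"; map them back
  num <- function(x) {
    if (is.null(x)) return(NA_real_)
    suppressWarnings(as.numeric(unlist(x)))
  }
  specs <- lapply(recs, function(r) {
    sensor_spec(r$name, r$pi0, r$R0, num(r$slopes), num(r$breaks),
                lam = num(r$lam),
                salt_in = r$salt_in, dye_conc_uM = r$dye_conc_uM,
                instrument = r$instrument, pi_max = r$pi_max)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}
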