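#' @title Emission spectra and the spectrofluorometer FRET ratio
#' @name spectra
#' @description Handling of fluorescence emission spectra recorded with
#'   458 nm excitation over 480-640 nm: background subtraction, the
#'   F562/F520 peak ratio, a two-band synthetic spectrum generator, and CSV
#'   input/output.
NULL

DONOR_NM <- 520
ACCEPTOR_NM <- 562

#' Construct an emission spectrum
#'
#' @param wavelengths Strictly increasing wavelength grid, nm; must cover
#'   both read-out wavelengths (520 and 562 nm).
#' @param intensities Detector counts, same length as `wavelengths`.
#' @param excitation_nm Excitation wavelength, nm.
#' @param bandwidth_nm Monochromator bandwidth, nm.
#' @param low_signal Logical flag set when the spectrum results from a
#'   subtraction that produced negative values.
#' @return Object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, excitation_nm = 458,
                              bandwidth_nm = 3.5, low_signal = FALSE) {
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (min(wavelengths) > DONOR_NM || max(wavelengths) < ACCEPTOR_NM)
    stop("wavelength grid must cover 520 and 562 nm")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 excitation_nm = excitation_nm,
                 bandwidth_nm = bandwidth_nm,
                 low_signal = isTRUE(low_signal)),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %g-%g nm (%d points), ex %g nm%s\n",
              min(x$wavelengths), max(x$wavelengths), length(x$wavelengths),
              x$excitation_nm, if (x$low_signal) " [low signal]" else ""))
  invisible(x)
}

# nearest grid point to a target wavelength, ties toward lower wavelength
nearest_index <- function(wavelengths, target) {
  d <- abs(wavelengths - target)
  which(d == min(d))[1]
}

#' Spectrofluorometer FRET ratio F562/F520
#'
#' Reads the emission intensity at the grid points nearest 562 nm
#' (sensitized acceptor emission) and 520 nm (donor emission) and returns
#' 100 * I(562)/I(520). Peak read-out uses single grid points, matching the
#' instrument convention of peak intensities rather than band integrals.
#'
#' @param s An [emission_spectrum()].
#' @return FRET ratio in %.
#' @export
fret_ratio_spectrum <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  i520 <- s$intensities[nearest_index(s$wavelengths, DONOR_NM)]
  i562 <- s$intensities[nearest_index(s$wavelengths, ACCEPTOR_NM)]
  if (i520 <= 0)
    stop("donor intensity at 520 nm is not positive; FRET ratio undefined")
  100 * i562 / i520
}

#' Subtract a background spectrum
#'
#' Pointwise subtraction of a matched background measurement (medium without
#' sensors) from a total-signal spectrum. Negative results are retained
#' (clamping would bias the ratio) but the returned spectrum is flagged
#' `low_signal`.
#'
#' @param sample,background [emission_spectrum()]s on identical grids.
#' @return An [emission_spectrum()] of the sensor-only signal.
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(background, "emission_spectrum"))
  if (length(sample$wavelengths) != length(background$wavelengths) ||
      any(sample$wavelengths != background$wavelengths))
    stop("sample and background wavelength grids differ")
  diff <- sample$intensities - background$intensities
  emission_spectrum(sample$wavelengths, diff,
                    excitation_nm = sample$excitation_nm,
                    bandwidth_nm = sample$bandwidth_nm,
                    low_signal = any(diff < 0))
}

#' Generate a synthetic two-band emission spectrum
#'
#' Two Gaussian emission bands centered at the donor (520 nm) and acceptor
#' (562 nm) read-out wavelengths on a 480-640 nm grid. The acceptor
#' amplitude is solved in closed form so that the noiseless
#' [fret_ratio_spectrum()] equals `ratio_target` exactly, accounting for the
#' overlap of each band at the other band's read-out wavelength.
#'
#' @param ratio_target Target FRET ratio, % (> 0).
#' @param donor_amp Donor band amplitude, counts.
#' @param widths Gaussian sigma of the donor and acceptor bands, nm
#'   (length 1 or 2).
#' @param noise_sd Additive Gaussian noise s.d., counts.
#' @param seed Integer RNG seed.
#' @param step_nm Grid step, nm.
#' @return An [emission_spectrum()].
#' @export
synth_spectrum <- function(ratio_target, donor_amp = 1000, widths = 15,
                           noise_sd = 0, seed = 1L, step_nm = 1) {
  if (ratio_target <= 0) stop("ratio_target must be > 0")
  widths <- rep(widths, length.out = 2)
  wl <- seq(480, 640, by = step_nm)
  rho <- ratio_target / 100
  # band j evaluated at the two read-out points
  g_d_at_a <- exp(-(ACCEPTOR_NM - DONOR_NM)^2 / (2 * widths[1]^2))
  g_a_at_d <- exp(-(DONOR_NM - ACCEPTOR_NM)^2 / (2 * widths[2]^2))
  denom <- 1 - rho * g_a_at_d
  acc_amp <- donor_amp * (rho - g_d_at_a) / denom
  if (denom <= 0 || acc_amp < 0)
    stop("band overlap too strong to realize the target ratio")
  inten <- donor_amp * exp(-(wl - DONOR_NM)^2 / (2 * widths[1]^2)) +
    acc_amp * exp(-(wl - ACCEPTOR_NM)^2 / (2 * widths[2]^2))
  if (noise_sd > 0) {
    set.seed(seed)
    inten <- inten + stats::rnorm(length(wl), 0, noise_sd)
  }
  emission_spectrum(wl, inten)
}

#' Read spectra from a long-format CSV
#'
#' Columns `wavelength_nm`, `intensity` and optionally `spectrum_id`; one
#' spectrum per id.
#'
#' @param path CSV file path.
#' @return Named list of [emission_spectrum()]s.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "intensity") %in% names(df)))
    stop("spectrum CSV needs columns wavelength_nm, intensity")
  if (!"spectrum_id" %in% names(df)) df$spectrum_id <- "spectrum"
  out <- lapply(split(df, df$spectrum_id), function(d) {
    d <- d[order(d$wavelength_nm), ]
    emission_spectrum(d$wavelength_nm, d$intensity)
  })
  out
}

#' Write spectra to a long-format CSV
#'
#' @param spectra Named list of [emission_spectrum()]s.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "emission_spectrum")) spectra <- list(spectrum = spectra)
  rows <- lapply(names(spectra), function(id) {
    s <- spectra[[id]]
    data.frame(spectrum_id = id, wavelength_nm = s$wavelengths,
               intensity = s$intensities)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
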