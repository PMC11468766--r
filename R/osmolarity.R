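#' @title Solution unit conversions
#' @name osmolarity
#' @description Conversions among NaCl mass fraction, molar concentration,
#'   osmolality and osmotic pressure, as used to prepare and characterize the
#'   standard solutions that calibrate the liposome sensors.
NULL

# Gas constant, J mol^-1 K^-1.  mol/L * J/mol = kPa, hence the /1000 to MPa.
RGAS <- 8.314

#' Molar mass of NaCl in g/mol
#' @export
MOLAR_MASS_NACL <- 58.44

#' Convert mass fraction to molarity
#'
#' Mass fraction is interpreted as mass-per-volume percent (g per 100 mL),
#' the clinical convention for saline under which 0.9% NaCl corresponds to
#' 154 mM. The conversion is purely stoichiometric.
#'
#' @param w Mass fraction in % (g per 100 mL). Non-negative.
#' @param molar_mass Solute molar mass in g/mol. Defaults to NaCl.
#' @return Molar concentration in mM.
#' @examples
#' mass_fraction_to_molarity(0.9) # 154 mM saline
#' @export
mass_fraction_to_molarity <- function(w, molar_mass = MOLAR_MASS_NACL) {
  if (any(w < 0)) stop("mass fraction must be >= 0")
  if (any(molar_mass <= 0)) stop("molar mass must be > 0")
  10 * w * 1000 / molar_mass
}

#' Convert molarity to mass fraction
#'
#' Inverse of [mass_fraction_to_molarity()].
#'
#' @param c_mM Molar concentration in mM. Non-negative.
#' @param molar_mass Solute molar mass in g/mol.
#' @return Mass fraction in % (g per 100 mL).
#' @export
molarity_to_mass_fraction <- function(c_mM, molar_mass = MOLAR_MASS_NACL) {
  if (any(c_mM < 0)) stop("molarity must be >= 0")
  if (any(molar_mass <= 0)) stop("molar mass must be > 0")
  c_mM * molar_mass / (10 * 1000)
}

#' Osmotic pressure of a NaCl solution (van't Hoff)
#'
#' Ideal-solution van't Hoff law for a fully dissociating 1:1 salt,
#' Pi = i * phi * c * R * T, with dissociation number i = 2 and osmotic
#' coefficient phi (default 0.93, the standard value for roughly isotonic
#' NaCl). 154 mM at 298.15 K gives approximately 0.7 MPa, the physiological
#' osmotic pressure.
#'
#' @param c_mM NaCl concentration in mM. Non-negative.
#' @param temperature_K Absolute temperature in K (default 298.15, room
#'   temperature; use 310.15 for incubator conditions).
#' @param phi Osmotic coefficient, dimensionless (default 0.93).
#' @param i Dissociation number (default 2 for NaCl).
#' @return Osmotic pressure in MPa. Linear in `c_mM`.
#' @examples
#' nacl_osmotic_pressure(154) # ~0.71 MPa
#' @export
nacl_osmotic_pressure <- function(c_mM, temperature_K = 298.15, phi = 0.93,
                                  i = 2L) {
  if (any(c_mM < 0)) stop("concentration must be >= 0")
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K")
  if (any(phi <= 0)) stop("osmotic coefficient must be > 0")
  if (any(i < 1)) stop("dissociation number must be >= 1")
  i * phi * (c_mM / 1000) * RGAS * temperature_K / 1000
}

#' Osmotic pressure from osmolality
#'
#' Converts an osmometer reading (freezing-point or vapor-pressure
#' depression, mOsm/kg) to osmotic pressure, approximating the solvent
#' density as 1 kg/L so that mOsm/kg maps onto osmol/L.
#'
#' @param b_mOsm Osmolality in mOsm/kg. Non-negative.
#' @param temperature_K Absolute temperature in K.
#' @return Osmotic pressure in MPa. Linear in `b_mOsm`.
#' @examples
#' osmolality_to_pressure(300) # ~0.74 MPa, near-isotonic standard
#' @export
osmolality_to_pressure <- function(b_mOsm, temperature_K = 298.15) {
  if (any(b_mOsm < 0)) stop("osmolality must be >= 0")
  if (any(temperature_K <= 0)) stop("temperature must be > 0 K")
  (b_mOsm / 1000) * RGAS * temperature_K / 1000
}

#' Osmotic pressure of a diluted medium
#'
#' Culture-medium osmotic pressure scales approximately linearly with medium
#' concentration, so an n-fold dilution divides the pressure by n.
#'
#' @param pi0 Osmotic pressure of the undiluted medium, MPa.
#' @param factor Dilution factor, >= 1 (2 for a 2x dilution).
#' @return Osmotic pressure of the diluted medium, MPa.
#' @examples
#' dilute_pressure(0.7, 2) # 2x diluted medium, ~0.35 MPa
#' @export
dilute_pressure <- function(pi0, factor) {
  if (any(factor < 1)) stop("dilution factor must be >= 1")
  pi0 / factor
}

#' Display-round a molarity
#'
#' Rounding convention for printed concentrations: nearest integer mM at or
#' above 100 mM, one decimal below.
#'
#' @param c_mM Molarity in mM.
#' @return Rounded numeric vector.
#' @export
format_molarity <- function(c_mM) {
  ifelse(c_mM >= 100, round(c_mM), round(c_mM, 1))
}

#' Fill in a solutions table
#'
#' Completes a table of solutions (columns `solute`, `mass_fraction_pct`,
#' `molarity_mM`, `temperature_K`, `phi`, `pressure_MPa`; missing values
#' allowed) by computing molarity from mass fraction (or vice versa) and the
#' van't Hoff pressure. Only NaCl rows are converted via molar mass; rows
#' with both concentration fields present are checked for consistency.
#'
#' @param solutions data.frame with at least one of `mass_fraction_pct`,
#'   `molarity_mM` per row.
#' @param molar_mass Solute molar mass used for the mass/molar conversion.
#' @return The completed data.frame.
#' @export
convert_solutions <- function(solutions, molar_mass = MOLAR_MASS_NACL) {
  stopifnot(is.data.frame(solutions))
  if (!"temperature_K" %in% names(solutions)) solutions$temperature_K <- 298.15
  if (!"phi" %in% names(solutions)) solutions$phi <- 0.93
  if (!"mass_fraction_pct" %in% names(solutions)) solutions$mass_fraction_pct <- NA_real_
  if (!"molarity_mM" %in% names(solutions)) solutions$molarity_mM <- NA_real_
  w <- solutions$mass_fraction_pct
  cm <- solutions$molarity_mM
  both <- !is.na(w) & !is.na(cm)
  if (any(both)) {
    implied <- mass_fraction_to_molarity(w[both], molar_mass)
    if (any(abs(implied - cm[both]) > pmax(1e-6, 1e-6 * implied)))
      stop("mass_fraction_pct and molarity_mM are inconsistent")
  }
  fill_m <- is.na(cm) & !is.na(w)
  cm[fill_m] <- mass_fraction_to_molarity(w[fill_m], molar_mass)
  fill_w <- is.na(w) & !is.na(cm)
  w[fill_w] <- molarity_to_mass_fraction(cm[fill_w], molar_mass)
  if (any(is.na(cm))) stop("each row needs mass_fraction_pct or molarity_mM")
  solutions$mass_fraction_pct <- w
  solutions$molarity_mM <- cm
  solutions$pressure_MPa <- nacl_osmotic_pressure(
    cm, solutions$temperature_K, solutions$phi)
  solutions
}
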