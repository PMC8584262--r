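# Physical constants (SI) and the unit conversions used throughout.
# Internal length unit is the angstrom, time the nanosecond, temperature kelvin;
# energies are handled in joules and converted at the reporting boundary.

#' Physical constants and unit conversions
#'
#' Boltzmann constant and Avogadro number (2019 SI exact values), plus the
#' conversion factors between the package's internal units (angstrom,
#' nanosecond) and the units membrane results are conventionally reported in
#' (nm, um^2/s, mN/m, J/mol).
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{NA_avogadro}{Avogadro number, 1/mol.}
#'   \item{A2_per_ns_to_um2_per_s}{multiply an MSD slope in A^2/ns to get um^2/s.}
#'   \item{J_per_A2_to_mN_per_m}{multiply an areal energy density in J/A^2 to get mN/m.}
#'   \item{mNm_A2_to_J}{multiply (mN/m) * A^2 to get J (isotherm work per molecule).}
#' }
#' @export
phys_const <- list(
  kB                     = 1.380649e-23,
  NA_avogadro            = 6.02214076e23,
  # 1 A^2/ns = 1e-20 m^2 / 1e-9 s = 1e-11 m^2/s = 10 um^2/s
  A2_per_ns_to_um2_per_s = 10,
  # 1 J/A^2 = 1e20 J/m^2 = 1e20 N/m = 1e23 mN/m
  J_per_A2_to_mN_per_m   = 1e23,
  # (1 mN/m) * (1 A^2) = 1e-3 N/m * 1e-20 m^2 = 1e-23 J
  mNm_A2_to_J            = 1e-23
)

#' Thermal energy
#'
#' @param temperature Temperature in kelvin.
#' @return kB*T in joules.
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  phys_const$kB * temperature
}

# Attach a unit tag to a numeric result; every public value carries one.
with_unit <- function(x, unit) {
  attr(x, "unit") <- unit
  x
}
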