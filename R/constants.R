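#' Physical constants and unit conventions
#'
#' Returns the fixed set of physical constants used throughout the package.
#' The internal energy unit is the wavenumber (cm^-1); time is in fs and
#' distances in Angstrom. Electronvolts appear only at presentation.
#'
#' @return A list with components:
#' \describe{
#'   \item{wavenumber_per_ev}{cm^-1 per eV (8065.544).}
#'   \item{boltzmann_wavenumber}{Boltzmann constant in cm^-1 per K (0.6950348).}
#'   \item{speed_of_light_cm_fs}{Speed of light in cm per fs (2.99792458e-5).}
#'   \item{dipole_coupling_prefactor}{Point-dipole coupling prefactor in
#'     cm^-1 A^3 / D^2 (5.034), the electrostatic conversion for transition
#'     dipoles in Debye, distances in Angstrom and energies in cm^-1.}
#' }
#' @examples
#' uc <- unit_constants()
#' uc$boltzmann_wavenumber * 300  # k_B T at 300 K, in cm^-1
#' @export
unit_constants <- function() {
  list(
    wavenumber_per_ev = 8065.544,
    boltzmann_wavenumber = 0.6950348,
    speed_of_light_cm_fs = 2.99792458e-5,
    dipole_coupling_prefactor = 5.034
  )
}

#' Energy unit conversions
#'
#' `cm1_to_ev()` and `ev_to_cm1()` convert between wavenumbers and
#' electronvolts using 1 eV = 8065.544 cm^-1.
#'
#' @param energy_cm1,energy_ev Numeric vector of energies.
#' @return Numeric vector of converted energies.
#' @examples
#' cm1_to_ev(11332)
#' ev_to_cm1(cm1_to_ev(11332))
#' @export
cm1_to_ev <- function(energy_cm1) energy_cm1 / unit_constants()$wavenumber_per_ev

#' @rdname cm1_to_ev
#' @export
ev_to_cm1 <- function(energy_ev) energy_ev * unit_constants()$wavenumber_per_ev

#' Timescale / frequency conversions for bath parameters
#'
#' Converts between a bath correlation timescale tau (fs) and the
#' corresponding cutoff frequency gamma (cm^-1) under the angular-frequency
#' convention gamma = 1 / (2 pi c tau). Under this convention a mean
#' correlation time of 16.065 fs corresponds to a cutoff of 330.5 cm^-1.
#'
#' @param tau_fs Timescale in fs (> 0).
#' @param gamma_cm1 Frequency in cm^-1 (> 0).
#' @return The converted quantity.
#' @examples
#' tau_to_gamma(16.065)
#' gamma_to_tau(tau_to_gamma(15))
#' @export
tau_to_gamma <- function(tau_fs) {
  stopifnot(is.numeric(tau_fs), all(tau_fs > 0))
  1 / (2 * pi * unit_constants()$speed_of_light_cm_fs * tau_fs)
}

#' @rdname tau_to_gamma
#' @export
gamma_to_tau <- function(gamma_cm1) {
  stopifnot(is.numeric(gamma_cm1), all(gamma_cm1 > 0))
  1 / (2 * pi * unit_constants()$speed_of_light_cm_fs * gamma_cm1)
}

#' Thermal energy in wavenumbers
#'
#' @param temperature Temperature in K (> 0).
#' @return k_B T in cm^-1.
#' @examples
#' kbt_cm1(300)
#' @export
kbt_cm1 <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  unit_constants()$boltzmann_wavenumber * temperature
}
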