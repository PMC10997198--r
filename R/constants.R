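# Physical constants (CODATA 2018) and the derived unit-conversion factors
# used throughout the package. All spectroscopic energies are wavenumbers
# (cm^-1), distances are Angstrom, dipoles are debye, rates are ps^-1.

.codata <- list(
  e   = 1.602176634e-19,   # elementary charge, C
  h   = 6.62607015e-34,    # Planck constant, J s
  c   = 2.99792458e8,      # speed of light, m/s
  kB  = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
  debye = 3.33564095e-30   # 1 D in C m
)

# hc in J cm: energy of 1 cm^-1
.hc_Jcm <- .codata$h * .codata$c * 100

#' Physical constants used by the coupling and rate calculators
#'
#' Returns the derived constants the package uses, each computed from CODATA
#' values rather than hard-coded:
#' \describe{
#'   \item{k_tresp}{Coulomb prefactor for transition-charge (TrEsp) couplings,
#'     in cm^-1 Angstrom e^-2: the interaction of two unit elementary charges
#'     1 Angstrom apart, in vacuum, expressed as a wavenumber
#'     (about 1.1614e5).}
#'   \item{c_pda}{Point-dipole prefactor in cm^-1 Angstrom^3 debye^-2
#'     (about 5034).}
#'   \item{kB_cm1}{Boltzmann constant in cm^-1/K (about 0.695035).}
#'   \item{ev_cm1}{1 eV in cm^-1 (about 8065.544).}
#' }
#'
#' @return Named list of numeric constants.
#' @export
#' @examples
#' physical_constants()$kB_cm1 * 300  # thermal energy at 300 K, cm^-1
physical_constants <- function() {
  with(.codata, list(
    k_tresp = e^2 / (4 * pi * eps0 * 1e-10) / .hc_Jcm,
    c_pda   = debye^2 / (4 * pi * eps0 * 1e-30) / .hc_Jcm,
    kB_cm1  = kB / .hc_Jcm,
    ev_cm1  = e / .hc_Jcm
  ))
}

.const <- local({
  p <- with(.codata, list(
    k_tresp = e^2 / (4 * pi * eps0 * 1e-10) / .hc_Jcm,
    c_pda   = debye^2 / (4 * pi * eps0 * 1e-30) / .hc_Jcm,
    kB_cm1  = kB / .hc_Jcm,
    ev_cm1  = e / .hc_Jcm,
    # 1 e Angstrom in debye (charge-times-distance dipole conversion)
    eA_debye = with(.codata, e * 1e-10 / debye)
  ))
  p
})

#' Unit conversions for spectroscopic energies
#'
#' Wavenumber (cm^-1) is the canonical energy unit of the package; these
#' helpers convert to and from electron volts and nanometres.
#'
#' @param ev,cm1,nm Numeric vectors in the unit named by the argument.
#' @return Numeric vector in the target unit.
#' @export
ev_to_cm1 <- function(ev) ev * .const$ev_cm1

#' @rdname ev_to_cm1
#' @export
cm1_to_ev <- function(cm1) cm1 / .const$ev_cm1

#' @rdname ev_to_cm1
#' @export
nm_to_cm1 <- function(nm) {
  stopifnot(all(nm > 0))
  1e7 / nm
}

#' @rdname ev_to_cm1
#' @export
cm1_to_nm <- function(cm1) {
  stopifnot(all(cm1 > 0))
  1e7 / cm1
}
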