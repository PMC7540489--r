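# Physical constants and unit conversions used throughout the package.
# Internal energy unit: wavenumbers (cm^-1); lengths: nm; dipoles: Debye;
# times: ps.

# speed of light in cm / ps (so that cm^-1 * cm/ps -> ps^-1 angular factors)
.c_cm_ps <- 2.99792458e-2

# Point-dipole coupling prefactor: energy in cm^-1 of two parallel 1 D dipoles
# 1 nm apart (kappa = 1, vacuum).  mu^2 / (4 pi eps0 R^3) / (h c).
.dipole_prefactor_cm1 <- local({
  debye <- 3.33564e-30                     # C m
  eps0 <- 8.8541878128e-12                 # F / m
  h <- 6.62607015e-34                      # J s
  c_cm <- 2.99792458e10                    # cm / s
  debye^2 / (4 * pi * eps0 * 1e-27) / (h * c_cm)
})

# gas constant in kJ / (mol K), for conformer Boltzmann weights
.R_kJ_mol_K <- 8.314462618e-3

#' Convert between wavelength and wavenumber
#'
#' Vacuum conversion `E = 10^7 / lambda` between wavelength in nanometres and
#' transition energy in wavenumbers (cm^-1). The transformation is its own
#' inverse, so a single function serves both directions.
#'
#' @param x Wavelength in nm, or energy in cm^-1.
#' @return Energy in cm^-1 (if `x` was nm) or wavelength in nm (if `x` was
#'   cm^-1).
#' @examples
#' nm_to_cm1(800)   # 12500 cm^-1
#' cm1_to_nm(12500) # 800 nm
#' @export
nm_to_cm1 <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  1e7 / x
}

#' @rdname nm_to_cm1
#' @export
cm1_to_nm <- nm_to_cm1
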