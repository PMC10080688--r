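#' Physical constants used throughout the package
#'
#' Returns the fixed set of physical constants used by the spectroscopic and
#' kinetic routines. All spectroscopic quantities in the package are handled
#' in wavenumbers (cm^-1), energies of classical sampling in kcal/mol,
#' distances in Angstrom, charges in units of the elementary charge.
#'
#' @return A named list:
#' \describe{
#'   \item{kB_cm1}{Boltzmann constant, 0.6950348 cm^-1 K^-1.}
#'   \item{kB_kcal}{Boltzmann constant, 1.9872041e-3 kcal mol^-1 K^-1.}
#'   \item{hbar_cm1_s}{Reduced Planck constant, 5.3088e-12 cm^-1 s.}
#'   \item{Ke_cm1_A_e2}{Coulomb constant for point charges,
#'     116140 cm^-1 Angstrom e^-2 (e^2/4 pi eps0 = 14.3996 eV Angstrom
#'     times 8065.54 cm^-1/eV), vacuum value.}
#' }
#' @examples
#' phys_constants()$kB_cm1 * 300  # thermal energy at 300 K, cm^-1
#' @export
phys_constants <- function() {
  list(
    kB_cm1      = 0.6950348,
    kB_kcal     = 1.9872041e-3,
    hbar_cm1_s  = 5.3088e-12,
    Ke_cm1_A_e2 = 116140
  )
}

.kB_cm1 <- 0.6950348
.kB_kcal <- 1.9872041e-3
.hbar_cm1_s <- 5.3088e-12
.Ke_cm1_A_e2 <- 116140
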