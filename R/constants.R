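#' Physical constants used throughout the package
#'
#' CODATA 2018 values in SI, plus the unit-bridging factors the estimators
#' need (kcal, amu, Angstrom, the Coulomb constant in kcal/mol e^-2 A).
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, J/K}
#'   \item{h, hbar}{Planck constant and reduced Planck constant, J s}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{amu}{atomic mass unit, kg}
#'   \item{kcal}{thermochemical kilocalorie, J}
#'   \item{coulomb_kcal}{Coulomb prefactor, kcal/mol per e^2/Angstrom}
#'   \item{kB_GPa_A3}{Boltzmann constant in GPa Angstrom^3 per K}
#'   \item{R_kcal}{molar gas constant, kcal/mol/K}
#' }
#' @export
pt_constants <- list(
  kB    = 1.380649e-23,
  h     = 6.62607015e-34,
  hbar  = 1.054571817e-34,
  N_A   = 6.02214076e23,
  amu   = 1.66053907e-27,
  kcal  = 4184,
  coulomb_kcal = 332.0637133,
  # 1 J = 1 Pa m^3 = 1e-9 GPa * 1e30 A^3 = 1e21 GPa A^3
  kB_GPa_A3 = 1.380649e-23 * 1e21,
  R_kcal = 1.380649e-23 * 6.02214076e23 / 4184
)

`%||%` <- function(a, b) if (is.null(a)) b else a
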