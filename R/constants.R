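#' Physical constants used throughout the package
#'
#' CODATA 2018 values in the package-wide unit system: lengths in nm,
#' energies in kJ/mol, charges in elementary charges, temperatures in K.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{kB}{Boltzmann constant as molar gas constant, kJ/mol/K.}
#'     \item{N_A}{Avogadro constant, 1/mol.}
#'     \item{e}{Elementary charge, C.}
#'     \item{eps0}{Vacuum permittivity, C^2/(J m).}
#'     \item{Faraday}{Faraday constant expressed as kJ/(mol V e), so that
#'       `z * Faraday * phi` is an energy in kJ/mol for a potential in V.}
#'     \item{f_coulomb}{Electric conversion factor e^2 N_A/(4 pi eps0) in
#'       kJ nm/mol; the Coulomb energy of two unit charges at 1 nm.}
#'     \item{xi_ew}{Dimensionless Wigner-lattice constant -2.837279 of the
#'       cubic periodic self-interaction potential.}
#'   }
#' @export
#' @examples
#' mgff_constants()$kB * 298.15 # thermal energy at room temperature, kJ/mol
mgff_constants <- function() {
  list(
    kB       = 0.008314462618,   # kJ/mol/K
    N_A      = 6.02214076e23,    # 1/mol
    e        = 1.602176634e-19,  # C
    eps0     = 8.8541878128e-12, # C^2 / (J m)
    Faraday  = 96.48533212,      # kJ/(mol V e)
    f_coulomb = 138.935458,      # kJ nm / mol
    xi_ew    = -2.837279
  )
}
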