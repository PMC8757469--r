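#' Finite-size (Wigner-lattice) correction to an ion charging free energy
#'
#' Under periodic boundary conditions a charged particle interacts with its
#' own images; the leading correction to the charging free energy in a
#' dielectric medium is
#' `- z^2 e^2 N_A xi_ew / (8 pi eps0 eps_r L)` with the cubic Wigner-lattice
#' constant `xi_ew = -2.837279`.  It scales as `z^2` and `1/L`.  An optional
#' excluded-volume sub-term proportional to `R1^2 / L^3` (the type-B cavity
#' correction) can be enabled; it is off by default and flagged in the
#' ledger metadata when used.
#'
#' @param z Integer valency.
#' @param L Cubic box edge length, nm.
#' @param eps_r Relative dielectric constant of the solvent model (>= 1).
#' @param R1 First-peak radius of the ion-water RDF, nm; only used by the
#'   excluded-volume term.
#' @param include_R1_term Enable the excluded-volume sub-term.
#' @return Correction in kJ/mol, to be added to the raw simulation value.
#' @export
#' @examples
#' finite_size_correction(z = 2, L = 4, eps_r = 68)
finite_size_correction <- function(z, L, eps_r, R1 = NULL,
                                   include_R1_term = FALSE) {
  if (L <= 0) stop("box length L must be positive", call. = FALSE)
  if (eps_r < 1) stop("eps_r must be >= 1", call. = FALSE)
  cst <- mgff_constants()
  # e^2 N_A / (8 pi eps0) = f_coulomb / 2, in kJ nm / mol
  lead <- -z^2 * cst$f_coulomb / (2 * eps_r) * cst$xi_ew / L
  if (include_R1_term) {
    if (is.null(R1)) stop("R1 required for the excluded-volume term", call. = FALSE)
    if (R1 <= 0 || R1 >= L / 2) stop("need 0 < R1 < L/2", call. = FALSE)
    lead <- lead + z^2 * cst$f_coulomb / (2 * eps_r) * (4 * pi / 3) * R1^2 / L^3
  }
  lead
}

#' Gas-compression correction
#'
#' Free energy of compressing the ideal gas from standard pressure `p0` to
#' the pressure `p1` of an ideal 1 mol/L solution: `kB T ln(p1/p0)`.
#' Independent of the water model; linear in T.
#'
#' @param T Temperature, K.
#' @param p0 Gas-phase reference pressure, atm (default 1).
#' @param p1 Ideal-solution pressure, atm (default 24.6, a 1 mol/L ideal
#'   solution at room temperature).
#' @return Correction in kJ/mol.
#' @export
compression_correction <- function(T = 298.15, p0 = 1, p1 = 24.6) {
  if (T <= 0) stop("T must be positive", call. = FALSE)
  if (p0 <= 0 || p1 <= 0) stop("pressures must be positive", call. = FALSE)
  mgff_constants()$kB * T * log(p1 / p0)
}

#' Interfacial-crossing (surface-potential) correction
#'
#' In the reference experiments the ion crosses the air-water interface and
#' picks up `z * F * phi_surf`.  Over any electroneutral set of ions the
#' term cancels exactly, which is why neutral-pair solvation free energies
#' are insensitive to the surface-potential convention.
#'
#' @param z Integer valency (vectorized).
#' @param phi_surf Air-water surface potential, V; default -0.527 V.
#' @return Correction in kJ/mol.
#' @export
#' @examples
#' sum(surface_correction(c(2, -1, -1))) # electroneutral set: zero
surface_correction <- function(z, phi_surf = -0.527) {
  z * mgff_constants()$Faraday * phi_surf
}

#' Assemble an itemized single-ion solvation free energy
#'
#' Adds the finite-size, compression, and (optionally) interfacial-crossing
#' corrections to a raw charging free energy from simulation.  With the
#' surface term included the result is comparable to surface-potential-
#' inclusive reference values (Tissandier convention); without it, to bulk
#' (Marcus) values.
#'
#' @param dG_raw Raw charging free energy from simulation, kJ/mol.
#' @param z Integer valency.
#' @param L Box edge, nm (NULL to skip the finite-size term).
#' @param eps_r Relative dielectric constant (with `L`).
#' @param R1 First-shell radius, nm (stored; used only by the optional
#'   excluded-volume sub-term).
#' @param T Temperature, K.
#' @param phi_surf Surface potential, V.
#' @param include_surface Include the interfacial-crossing term.
#' @param include_compression Include the gas-compression term.
#' @param include_R1_term Enable the finite-size excluded-volume sub-term.
#' @return Object of class `SolvationLedger`: the itemized terms and their
#'   exact sum `dG_solv`.
#' @export
#' @examples
#' assemble_single_ion(-1950, z = 2, L = 4, eps_r = 68, R1 = 0.209)
assemble_single_ion <- function(dG_raw, z, L = NULL, eps_r = NULL, R1 = NA,
                                T = 298.15, phi_surf = -0.527,
                                include_surface = TRUE,
                                include_compression = TRUE,
                                include_R1_term = FALSE) {
  stopifnot(is.finite(dG_raw))
  fs <- if (!is.null(L) && z != 0) {
    finite_size_correction(z, L, eps_r, R1 = if (is.na(R1)) NULL else R1,
                           include_R1_term = include_R1_term)
  } else 0
  comp <- if (include_compression) compression_correction(T) else 0
  surf <- if (include_surface && z != 0) surface_correction(z, phi_surf) else 0
  structure(list(
    ion = if (z > 0) "cation" else if (z < 0) "anion" else "neutral",
    z = as.integer(z), dG_raw = dG_raw,
    dG_finite_size = fs, dG_compression = comp, dG_surface = surf,
    dG_solv = dG_raw + fs + comp + surf,
    box_L = L %||% NA_real_, eps_r = eps_r %||% NA_real_, R1 = R1, T = T,
    include_surface = include_surface, include_R1_term = include_R1_term
  ), class = "SolvationLedger")
}

#' @export
print.SolvationLedger <- function(x, ...) {
  cat(sprintf("<SolvationLedger> z = %+d (T = %g K)\n", x$z, x$T))
  cat(sprintf("  raw charging      %10.2f kJ/mol\n", x$dG_raw))
  cat(sprintf("  finite size       %10.2f kJ/mol\n", x$dG_finite_size))
  cat(sprintf("  compression       %10.2f kJ/mol\n", x$dG_compression))
  cat(sprintf("  interfacial       %10.2f kJ/mol%s\n", x$dG_surface,
              if (x$include_surface) "" else " (off)"))
  cat(sprintf("  dG_solv           %10.2f kJ/mol\n", x$dG_solv))
  invisible(x)
}

#' @export
as.data.frame.SolvationLedger <- function(x, ...) {
  data.frame(z = x$z, dG_raw = x$dG_raw, dG_finite_size = x$dG_finite_size,
             dG_compression = x$dG_compression, dG_surface = x$dG_surface,
             dG_solv = x$dG_solv, box_L = x$box_L, eps_r = x$eps_r,
             R1 = x$R1, T = x$T)
}

#' Neutral-salt solvation free energy from single-ion values
#'
#' `dG_solv(MgCl2) = dG_solv(Mg2+) + 2 dG_solv(Cl-)`.  Accepts numbers or
#' `SolvationLedger` objects; ledgers under different surface-term
#' conventions are rejected, and within the sum the surface contributions
#' cancel by electroneutrality.
#'
#' @param dG_Mg Cation solvation free energy (kJ/mol) or its ledger.
#' @param dG_Cl Anion solvation free energy (kJ/mol) or its ledger;
#'   counted twice.
#' @return Salt solvation free energy, kJ/mol.
#' @export
#' @examples
#' assemble_salt(-1923.6, -304.2)
assemble_salt <- function(dG_Mg, dG_Cl) {
  led <- inherits(dG_Mg, "SolvationLedger") || inherits(dG_Cl, "SolvationLedger")
  if (led) {
    if (!(inherits(dG_Mg, "SolvationLedger") && inherits(dG_Cl, "SolvationLedger")))
      stop("mixing a ledger with a bare number; pass both as ledgers", call. = FALSE)
    if (!identical(dG_Mg$include_surface, dG_Cl$include_surface))
      stop("ledgers use different surface-term conventions", call. = FALSE)
    if (dG_Mg$z + 2 * dG_Cl$z != 0)
      stop("ledgers do not form an electroneutral MgCl2 unit", call. = FALSE)
    return(dG_Mg$dG_solv + 2 * dG_Cl$dG_solv)
  }
  dG_Mg + 2 * dG_Cl
}
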