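#' Effective pair interaction produced by (scaled) combination rules
#'
#' @param atoms Character vector of length 2 with the partner labels.
#' @param sigma_pair LJ diameter of the pair, nm.
#' @param eps_pair LJ well depth of the pair, kJ/mol.
#' @param c4 Optional attractive `C4/r^4` coefficient (kJ nm^4/mol) for
#'   comparison against 12-6-4 literature potentials; 0 for the plain
#'   12-6 form.
#' @param charges Integer charges of the two partners, elementary charges.
#' @return Object of class `PairInteraction`.
#' @export
pair_interaction <- function(atoms, sigma_pair, eps_pair, c4 = 0,
                             charges = c(0L, 0L)) {
  stopifnot(length(atoms) == 2, sigma_pair > 0, eps_pair >= 0, c4 >= 0)
  structure(list(atoms = atoms, sigma_pair = sigma_pair, eps_pair = eps_pair,
                 c4 = c4, charges = as.integer(charges)),
            class = "PairInteraction")
}

#' @export
print.PairInteraction <- function(x, ...) {
  cat(sprintf("<PairInteraction> %s-%s: sigma %.6g nm, eps %.6g kJ/mol",
              x$atoms[1], x$atoms[2], x$sigma_pair, x$eps_pair))
  if (x$c4 > 0) cat(sprintf(", C4 %.6g kJ nm^4/mol", x$c4))
  cat("\n"); invisible(x)
}

# Extract (sigma, eps, charge, label) from an IonLJSet, a row of the RNA
# atom-type table, or a bare list(sigma=, eps=).
.lj_partner <- function(x) {
  if (inherits(x, "IonLJSet"))
    return(list(sigma = x$sigma_ii, eps = x$eps_ii, charge = x$charge,
                label = x$ion))
  if (is.list(x) || is.data.frame(x)) {
    x <- as.list(x)
    sigma <- x$sigma %||% x$sigma_ii
    eps <- x$eps %||% x$eps_ii
    if (is.null(sigma) || is.null(eps))
      stop("combination-rule partner needs 'sigma' and 'eps'", call. = FALSE)
    return(list(sigma = sigma, eps = eps, charge = x$charge %||% 0L,
                label = x$type %||% x$label %||% "X"))
  }
  stop("unsupported combination-rule partner", call. = FALSE)
}

#' Scaled Lorentz-Berthelot combination rules
#'
#' Computes the effective pair parameters
#' `sigma_pair = lambda_sigma * (sigma_a + sigma_b)/2`,
#' `eps_pair = lambda_eps * sqrt(eps_a * eps_b)`.  With identity factors
#' this is the standard Lorentz-Berthelot rule; scaled factors compensate
#' for the missing polarizability and charge-transfer response of fixed-
#' charge models in cation-anion and cation-RNA pairs.
#'
#' @param a,b Partners: `IonLJSet` objects, rows of the RNA atom-type table,
#'   or lists with `sigma` (nm) and `eps` (kJ/mol) fields.
#' @param s A `ScalingFactors` object; defaults to the identity.
#' @return A `PairInteraction`.  Commutative in `(a, b)`.
#' @export
#' @examples
#' scaled_lb(list(sigma = 0.2, eps = 4), list(sigma = 0.3, eps = 4))
scaled_lb <- function(a, b, s = scaling_factors()) {
  pa <- .lj_partner(a); pb <- .lj_partner(b)
  if (!inherits(s, "ScalingFactors")) stop("s must be ScalingFactors", call. = FALSE)
  if (pa$sigma <= 0 || pb$sigma <= 0)
    stop("combination rule requires positive sigma", call. = FALSE)
  pair_interaction(c(pa$label, pb$label),
                   sigma_pair = s$lambda_sigma * (pa$sigma + pb$sigma) / 2,
                   eps_pair = s$lambda_eps * sqrt(pa$eps * pb$eps),
                   charges = c(pa$charge, pb$charge))
}

#' Invert the standard Lorentz-Berthelot rule against a water model
#'
#' Recovers ion-ion parameters from ion-water-oxygen values:
#' `sigma_ii = 2 sigma_io - sigma_OO`, `eps_ii = eps_io^2 / eps_OO`.
#' The round trip with the forward rule is the identity to machine
#' precision.
#'
#' @param water A `WaterModel`.
#' @param sigma_io Ion-oxygen LJ diameter, nm (optional).
#' @param eps_io Ion-oxygen LJ well depth, kJ/mol (optional).
#' @param use_published Use the originally published water constants instead
#'   of the registry defaults implied by the optimized tables.
#' @return Named list with whichever of `sigma_ii`, `eps_ii` was requested.
#' @export
#' @examples
#' reg <- load_registry()
#' invert_lb(water_model(reg, "SPC/E"), sigma_io = 0.378)
invert_lb <- function(water, sigma_io = NULL, eps_io = NULL,
                      use_published = FALSE) {
  stopifnot(inherits(water, "WaterModel"))
  sOO <- if (use_published) water$sigma_OO_published else water$sigma_OO
  eOO <- if (use_published) water$eps_OO_published else water$eps_OO
  out <- list()
  if (!is.null(sigma_io)) {
    sii <- 2 * sigma_io - sOO
    if (any(sii <= 0)) stop("inverted sigma_ii is nonpositive", call. = FALSE)
    out$sigma_ii <- sii
  }
  if (!is.null(eps_io)) {
    if (any(eps_io < 0)) stop("eps_io must be nonnegative", call. = FALSE)
    out$eps_ii <- eps_io^2 / eOO
  }
  if (!length(out)) stop("provide sigma_io and/or eps_io", call. = FALSE)
  out
}

#' Lennard-Jones (optionally 12-6-4 and Coulomb) pair energy
#'
#' `V(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] - C4/r^4`, plus the Coulomb
#' term `q_i q_j f / (eps_medium r)` when requested (`f` is the electric
#' conversion factor in kJ nm/mol).  Vectorized over `r`.
#'
#' @param p A `PairInteraction`.
#' @param r Distances, nm; all positive.
#' @param include_coulomb Add the point-charge Coulomb term.
#' @param medium_eps Relative dielectric constant screening the Coulomb term.
#' @return Energies in kJ/mol, same length as `r`.
#' @export
#' @examples
#' p <- pair_interaction(c("Mg", "O"), 0.21, 10)
#' lj_energy(p, 2^(1/6) * 0.21) # the LJ minimum, -eps
lj_energy <- function(p, r, include_coulomb = FALSE, medium_eps = 1) {
  stopifnot(inherits(p, "PairInteraction"))
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  sr6 <- (p$sigma_pair / r)^6
  v <- 4 * p$eps_pair * (sr6^2 - sr6) - p$c4 / r^4
  if (include_coulomb) {
    cst <- mgff_constants()
    v <- v + p$charges[1] * p$charges[2] * cst$f_coulomb / (medium_eps * r)
  }
  v
}

#' Reproduce the published pair-parameter columns from the registry
#'
#' Applies the scaled combination rules to every optimized Mg2+ set and its
#' Cl- reference / RNA phosphate-oxygen partner, giving the Mg-Cl and Mg-OP
#' pair columns of the published parameter table.
#'
#' @param reg A `Registry`.
#' @param use_reconstructed Use full-precision Mg `sigma_ii` reconstructed as
#'   `2 sigma_io - sigma_OO` for the Mg-Cl pair (default); the printed
#'   4-decimal values lose the digit that decides the fourth decimal of some
#'   pair sigmas.  The Mg-OP columns round from the printed values and are
#'   always computed from them.
#' @return Data frame with one row per (variant, water) and computed
#'   `sigma_MgCl`, `eps_MgCl`, `sigma_MgOP`, `eps_MgOP` (NA where the
#'   registry has no Cl- partner for that water).
#' @export
pair_table <- function(reg, use_reconstructed = TRUE) {
  o2 <- reg$rna_atomtypes[reg$rna_atomtypes$type == "O2", ]
  rows <- lapply(names(reg$ion_sets), function(key) {
    mg <- reg$ion_sets[[key]]
    if (mg$ion != "Mg") return(NULL)
    w <- reg$water_models[[mg$water]]
    part <- mg
    if (use_reconstructed)
      part$sigma_ii <- reconstructed_ii(mg, w)$sigma_ii
    cl <- reg$cl_sets[[mg$water]]
    s_cl <- e_cl <- NA_real_
    if (!is.null(cl)) {
      p <- scaled_lb(part, cl, scaling_for(reg, mg$variant, mg$water, "Cl"))
      s_cl <- p$sigma_pair; e_cl <- p$eps_pair
    }
    p2 <- scaled_lb(mg, o2, scaling_for(reg, mg$variant, mg$water, "RNA"))
    data.frame(variant = mg$variant, water = mg$water,
               sigma_MgCl = s_cl, eps_MgCl = e_cl,
               sigma_MgOP = p2$sigma_pair, eps_MgOP = p2$eps_pair,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
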