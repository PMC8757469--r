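#' Kirkwood-Buff integral of an RDF
#'
#' `G(r_cut) = 4 pi Int_0^r_cut (g(r) - 1) r^2 dr` by the trapezoid rule on
#' bin centers, with the running profile returned so convergence in `r_cut`
#' can be inspected.  Plain truncation; no tail-model extrapolation.
#'
#' @param rdf An `RDFCurve`.
#' @param r_cut Truncation radius, nm; must lie inside the tabulated range.
#' @return List with `G` (nm^3) and `profile`, a data frame of `r` and the
#'   running integral `G_r`.
#' @export
#' @examples
#' r <- seq(0.005, 2, by = 0.01)
#' flat <- rdf_curve(r, rep(1, length(r)), rho_partner = 33, bin_width = 0.01)
#' kb_integral(flat, 1.5)$G # ideal gas: zero
kb_integral <- function(rdf, r_cut) {
  stopifnot(inherits(rdf, "RDFCurve"))
  r <- rdf$r_centers
  if (r_cut > max(r) + rdf$bin_width / 2 + 1e-9)
    stop(sprintf("r_cut = %.4g nm beyond tabulated range (%.4g nm)",
                 r_cut, max(r)), call. = FALSE)
  sel <- r <= r_cut
  x <- r[sel]; y <- 4 * pi * (rdf$g[sel] - 1) * x^2
  if (sum(sel) < 2) stop("r_cut leaves fewer than 2 bins", call. = FALSE)
  cum <- c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
  list(G = cum[length(cum)], profile = data.frame(r = x, G_r = cum))
}

#' Number-weighted salt-salt Kirkwood-Buff integral
#'
#' Treats cation and anion as indistinguishable salt particles: for a 1:2
#' electrolyte the salt-salt integral is the number-weighted average of the
#' ion-ion integrals with weights 1/9 (+ +), 4/9 (+ -), 4/9 (- -).
#'
#' @param G_pp,G_pm,G_mm Cation-cation, cation-anion, anion-anion KB
#'   integrals, nm^3.
#' @param nu_p,nu_m Stoichiometric coefficients (default 1:2).
#' @return Salt-salt integral `G_cc`, nm^3.
#' @export
salt_kb_average <- function(G_pp, G_pm, G_mm, nu_p = 1, nu_m = 2) {
  nu <- nu_p + nu_m
  (nu_p^2 * G_pp + 2 * nu_p * nu_m * G_pm + nu_m^2 * G_mm) / nu^2
}

#' Bundle Kirkwood-Buff integrals for the activity derivative
#'
#' @param G_cc Salt-salt KB integral (indistinguishable-ion convention),
#'   nm^3.
#' @param G_cw Salt-water KB integral, nm^3.
#' @param rho_c Salt number density, nm^-3.
#' @param G_ww Water-water KB integral, nm^3 (optional).
#' @param r_cut Truncation radius the integrals were evaluated at, nm.
#' @return Object of class `KBSet`.
#' @export
kb_set <- function(G_cc, G_cw, rho_c, G_ww = NA_real_, r_cut = NA_real_) {
  stopifnot(is.finite(G_cc), is.finite(G_cw), rho_c >= 0)
  structure(list(G_cc = G_cc, G_cw = G_cw, G_ww = G_ww, rho_c = rho_c,
                 r_cut = r_cut), class = "KBSet")
}

#' Activity derivative of the salt from Kirkwood-Buff integrals
#'
#' For a binary solution the derivative of the salt activity with respect
#' to the logarithm of its number density is
#' `a_cc = 1 / (1 + rho_c (G_cc - G_cw))`; ideal solutions give exactly 1.
#' The denominator must stay positive for a thermodynamically stable
#' solution.
#'
#' @param kb A `KBSet`.
#' @return `a_cc`, dimensionless.
#' @export
#' @examples
#' activity_derivative(kb_set(G_cc = -0.5, G_cw = 0, rho_c = 0.15))
activity_derivative <- function(kb) {
  stopifnot(inherits(kb, "KBSet"))
  den <- 1 + kb$rho_c * (kb$G_cc - kb$G_cw)
  if (den <= 0)
    stop(sprintf("non-physical KB set: 1 + rho_c (G_cc - G_cw) = %.4g <= 0", den),
         call. = FALSE)
  1 / den
}
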