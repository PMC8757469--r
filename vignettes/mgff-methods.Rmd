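---
title: "Methods: magnesium force-field parametrization and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnesium force-field parametrization and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgff)
```

## The problem

Mg²⁺ is small, doubly charged, and strongly polarizes its surroundings.
Fixed-charge 12-6 Lennard-Jones models fitted to one or two bulk
observables typically get the rest wrong: hydration free energy, shell
radius, coordination number, water-exchange kinetics, ion-pair activity
and binding to nucleic-acid phosphates cannot all be matched by the two
parameters of an ion–water LJ potential combined with standard mixing
rules.  The approach implemented here decouples the problem: the
ion–water interaction (σ_io, ε_io) is fitted first against single-ion
observables on a grid, the exchange kinetics selects among the surviving
candidates, and the cation–anion and cation–phosphate interactions are
then corrected independently by scaling the Lorentz–Berthelot
combination rules,

σ_ij = λ_σ (σ_i + σ_j)/2,  ε_ij = λ_ε √(ε_i ε_j),

with λ = 1 recovering the standard rules.  Because λ only touches
unlike-pair terms, the single-ion properties fixed in the first stages
are exactly preserved.  The package ships the resulting parameter
registry for six rigid water models (TIP3P, SPC/E, TIP3P-fb, TIP4P/2005,
TIP4P-Ew, TIP4P-D), two Mg²⁺ variants per water (*microMg*: realistic
microsecond exchange; *nanoMg*: accelerated exchange for sampling), the
Cl⁻ reference sets, and all estimators needed to evaluate a candidate
parameter set on simulation output — plus synthetic-data generators with
planted ground truth so every estimator is testable without running MD.

Units everywhere: nm, kJ/mol, elementary charges, Kelvin; free-energy
profiles and binding affinities in k~B~T.

## Parameter registry and reproduction of the published tables

`load_registry()` stores the printed parameter values with provenance
strings.  Two details matter when reproducing the published pair
columns:

* The printed ion σ_ii are rounded to 4 decimals, but the published
  Mg–Cl pair σ were computed from unrounded values.  The lost digit is
  recovered by inverting the combination rule against the water oxygen,
  σ_ii = 2σ_io − σ_OO (`reconstructed_ii()`).  `pair_table()` uses the
  reconstruction for the Mg–Cl columns; the Mg–phosphate columns round
  from the printed values and are computed from them directly.
* The water constants used in that reconstruction are the values implied
  by the tables themselves (2σ_io − σ_ii and ε_io²/ε_ii agree between
  the microMg and nanoMg rows to 10⁻⁴ nm / 0.1 %, which
  `validate_registry()` checks).  For TIP4P-D the implied constants
  (σ_OO ≈ 0.3154 nm, ε_OO ≈ 0.6487 kJ/mol) differ from the commonly
  cited model constants (0.3165 / 0.9366); the registry stores the
  implied values as defaults and the published ones alongside, because
  the Cl⁻ reference set for TIP4P-D is only combination-rule-consistent
  with the published constants.

Three printed pair-column cells contradict the λ values printed in
their own rows (no evaluation of the scaling rule can reproduce them);
`pair_table()` returns the values consistent with the printed λ, and the
test suite pins the discrepancy explicitly rather than papering over it.

Topology export (`export_itp()`) writes GROMACS σ/ε-convention
fragments with explicit `[nonbond_params]` overrides for every scaled
pair, because λ ≠ 1 cannot be expressed through a global combination
rule; 17-significant-digit formatting makes the export/parse round trip
bit-exact.

## Solvation free-energy corrections

Raw charging free energies from periodic simulations need three
corrections before they can be compared with experiment
(`assemble_single_ion()` itemizes them in a ledger that sums exactly):

* **Finite size**: the Wigner-lattice self-interaction of a charge in a
  periodic dielectric, −z²e²N_A ξ_ew/(8πϵ₀ϵ_r L) with ξ_ew = −2.837279;
  scales as z² and 1/L.  An excluded-volume sub-term ∝ R₁²/L³ is
  available behind `include_R1_term` and is off by default — its exact
  published form is not recoverable from the source text, so the choice
  is surfaced in the ledger metadata rather than silently applied.
* **Compression**: k_B T ln(p₁/p₀) with p₁ = 24.6 atm (ideal 1 mol/L
  solution), water-model independent.
* **Interfacial crossing**: z·F·ϕ_surf with ϕ_surf = −0.527 V.  Over
  any electroneutral ion set this cancels exactly, which is why the
  package works with neutral-pair solvation free energies
  (`assemble_salt()`: ΔG(MgCl₂) = ΔG(Mg²⁺) + 2ΔG(Cl⁻)) — they are
  independent of both the surface-potential and the proton-reference
  conventions.  With the surface term included single-ion values are
  comparable to surface-inclusive (Tissandier-type) references; without
  it, to bulk (Marcus-type) references.

## Hydration structure

`compute_rdf()` is a standard shell-volume-normalized minimum-image
histogram (orthorhombic boxes only; default bin 0.002 nm, chosen to
resolve the ±0.004 nm experimental uncertainty on the shell radius).
`shell_summary()` takes R₁ as the argmax of the first region where
g > 2 (divalent shells exceed this by orders of magnitude; the threshold
is configurable), locates the first minimum by the sign change of a
3-bin-smoothed discrete derivative (tie-break: smallest r) — the first
*local* minimum, since the source does not state which minimum bounds
the coordination integral — and integrates n₁ = 4πρ∫g r² dr by the
trapezoid rule on bin centers.  `diffusion_coefficient()` fits the
Einstein relation MSD = 6Dt over a lag window, with block-resampled
uncertainty and a log–log slope diagnostic that flags non-diffusive
(e.g. ballistic) input; no hydrodynamic finite-size correction is
applied, matching the practice of the reference workflow.

## Water-exchange kinetics

Exchange events are counted with a dual-cutoff (hysteresis) scheme
(`assign_and_count()`): a water commits to the shell only below r_core
and to the bulk only above r_out, so barrier recrossings in between are
ignored — single-cutoff transition-state counting can overestimate
rates by orders of magnitude.  Defaults: r_core at the first RDF
minimum, r_out = r_core + 0.04 nm.  The rate convention is

k = N / (N_ion · n₁ · t_sim),

i.e. committed crossings per second, per ion, per shell water, with
n₁ = 6 fixed by default (a time-averaged occupancy may be supplied).
This convention reproduces every published N↔k pair to ≈1 % with
N_ion = 78 and t = 1 μs.  One true swap produces two committed
crossings (the exit of the leaving and the entry of the entering
water) — across two different waters, one per water.  Uncertainties
come from block averaging (default 5 contiguous blocks).

## Kirkwood–Buff activity derivative

`kb_integral()` truncates G(r_cut) = 4π∫(g−1)r²dr at a user-chosen
radius and exposes the running profile for convergence inspection; no
tail extrapolation is applied.  Cations and anions are treated as
indistinguishable salt particles: for the 1:2 electrolyte
`salt_kb_average()` weights the ++, +−, −− integrals by 1/9, 4/9, 4/9.
The activity derivative uses the binary-solution Kirkwood–Buff form

a_cc = 1 / (1 + ρ_c (G_cc − G_cw)),

exactly 1 for ideal fixtures and strictly decreasing in the salt–salt
excess.  The exact combination used in the original supplementary
material is not recoverable from the main text; the adopted form is the
standard constant-(T,p) binary result, and the fixtures pin it.

## Free energies: WHAM, TI/BAR, binding

`wham_1d()` implements classic binned WHAM: histogram counts H_b,
window bias factors c_ib, self-consistent iteration of
P_b = H_b / Σ_i n_i f_i c_ib and f_i⁻¹ = Σ_b c_ib P_b to a tolerance of
10⁻⁷ on the window constants (cap 10⁵ iterations).  Bias factors are
bin-averaged with a 5-point midpoint rule so that stiff springs do not
bias the estimate through within-bin curvature.  A single unbiased
window reduces exactly to Boltzmann inversion of the histogram;
disconnected window coverage raises an error naming the gap.
`profile_features()` reads the binding distance R_b (first minimum) and
barrier ΔF\* (first interior maximum after it) off the grid without
interpolation, ties toward smaller r; for estimated (noisy) profiles a
prominence criterion (`min_prominence`, in k~B~T) suppresses
noise-induced extrema.

For the double-well recovery experiments the umbrella spring must
exceed the largest negative curvature of the profile (here
|F''| ≈ 2700 k~B~T/nm² for the 15 k~B~T well): softer springs leave
barrier-top windows bimodal and the profile noisy.  The shipped
experiments use k = 10⁴ kJ/mol/nm², 20 windows spanning the wells,
5000 samples per window and 120 bins; at these sizes the recovery RMSE
stays below 0.2 k~B~T and the barrier error below 0.3 k~B~T across
seeds, and the whole experiment runs in seconds.

`alchemical_dG()` provides thermodynamic integration (trapezoid over
per-λ means with block standard errors propagated through the
quadrature weights) and Bennett's acceptance ratio (self-consistent
Fermi-function estimator with the asymptotic variance) as mutual
cross-checks.  Standard-state corrections for absolute binding free
energies are deliberately an explicit input rather than silently
computed; experimental comparisons go through the stability constant,
ΔG_b⁰ = −ln(10)·logK k~B~T.

## The three-step selector

Stage 1 (`feasible_set()`): every (σ_io, ε_io) node whose tabulated
ΔG_solv, R₁ and n₁ pass their targets — evaluation strictly at grid
nodes, no interpolation, deterministic lexicographic order.  The
default ΔG_solv tolerance is ±1 kJ/mol (the error bar the reference
tables print); it is configurable.  Stage 2 (`select_micro_nano()`):
*micro* is the feasible node log-nearest to the midpoint of the
experimental exchange-rate range (the source states only that it
"matches" the experimental rate; log-nearest formalizes that), *nano*
the feasible argmax, ties toward smaller ε_io then σ_io.  Stage 3
(`scan_lambda()`): among λ nodes passing hard tolerances, minimize the
tolerance-normalized weighted squared deviation; a no-pass scan errors
with a nearest-miss report instead of silently picking.

## Synthetic data and what it does (not) show

Every generator is a pure function of (parameters, seed) and ships its
ground truth alongside the data:

* `gen_toy_trajectory()`: event-driven (Gillespie-clock) shell
  exchanges — no time-discretization bias in the planted rate; slot
  events fire at exchange_rate/2 so the crossing counter, which sees an
  exit plus an entry per swap, measures exchange_rate per shell water.
  Defaults mirror the Mg²⁺ study conditions: n₁ = 6, R₁ = 0.209 nm,
  1 μs observation; sampling every 400 ps resolves the planted rates
  used in the tests with <2 % detection loss (the generator warns when
  dt approaches the mean waiting time).
* `gen_rdf()`: Gaussian first-shell peak of prescribed occupancy plus a
  smoothly switched exponential baseline, with closed-form shell and
  Kirkwood–Buff integrals for oracle comparison.
* `gen_umbrella_samples()`: rejection sampling from the biased
  densities against a uniform proposal with a grid-located envelope
  (exact for arbitrary profiles, at the cost of acceptance rate).
* `gen_property_surfaces()`: quadratic-bowl responses scaled to the
  grid step so exactly the planted node passes the default targets at
  zero noise; noise is expressed relative to the one-step response
  increment, so 1 % noise cannot move the selection by more than a
  grid step.

These generators emulate first-shell phenomenology, ideal Poisson
kinetics and smooth response surfaces.  They do not mimic real water
structure beyond the first shell, concerted two-water exchange
mechanisms, correlated noise in MD observables, or force evaluation of
any kind — passing the recovery tests therefore validates the
*estimators*, not the physics of any particular simulation.  Property
values that require actual MD (simulated ΔG_solv, exchange rates,
activity derivatives of real parameter sets) are outside what this
package can recompute.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* Binned WHAM only (no unbinned/MBAR estimator); 1-D profiles only.
* The Kirkwood–Buff route truncates at r_cut; long-range tail models
  are intentionally not fitted.
* The registry's TIP3P rows come from an earlier parametrization with
  a different Cl⁻ partner and different rounding; they are carried for
  completeness but excluded from the 4-decimal reproduction guarantees.
* No 12-6-4 parameter fitting: the C4 term exists only to plot and
  compare literature potentials.
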