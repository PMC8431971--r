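---
title: "Pair-specific Lennard-Jones corrections for cation-sulfur interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pair-specific Lennard-Jones corrections for cation-sulfur interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbfixr)
```

## The problem

Sodium-coupled glutamate-transporter homologs coordinate one of their three
Na⁺ ions — the one in the so-called Na2 site — partly through the thioether
sulfur of a conserved methionine. A thioether is nominally hydrophobic, and
fixed-charge force fields of the CHARMM family treat it as such: the
partial charges are constant, so the electronic polarization of the sulfur
by an approaching cation is entirely absent. The molecular-mechanics
S–Na⁺ dimer curve is therefore far too shallow, and simulations of the
transporter show quick, spurious loss of the Na2 ion.

The accepted remedy does not touch the charges (which would perturb every
methionine interaction in the system). Instead it overrides the
Lennard-Jones parameters of the *single* S–Na⁺ atom-type pair — an NBFIX
correction — so that the dimer curve matches a reference ion–thioether
potential-energy scan. `nbfixr` implements this fit and the supporting
analyses: dimer scans, parameter file I/O, structure mining for
cation–sulfur contacts, reversal-potential assay design, and
binding-site trajectory analysis. Quantum-chemistry scans, molecular
dynamics engines and the wet lab are outside its scope; where their outputs
are needed as inputs, seed-deterministic synthetic generators with known
ground truth stand in for them.

## The dimer energy model

`pair_interaction_energy()` evaluates, for a rigid molecular analog and a
monatomic ion,

$$E = \sum_i \left[ \frac{k_e\, q_i\, q_\mathrm{ion}}{r_i}
  + \varepsilon_{ij}\left( \left(\tfrac{R_{\min,ij}}{r_i}\right)^{12}
  - 2 \left(\tfrac{R_{\min,ij}}{r_i}\right)^{6} \right) \right]$$

with $k_e = 332.0636$ kcal·Å/(mol·e²) (the CHARMM convention; relative
dielectric 1) and $\varepsilon_{ij}$ entering as a negative well, so an
isolated neutral pair has its minimum $-\varepsilon_{ij}$ exactly at
$R_{\min,ij}$. Pair parameters come from Lorentz–Berthelot combination —
geometric-mean well depth, arithmetic sum of per-type $R_{\min}/2$ — unless
an override exists for the pair, in which case the override is used
verbatim. No cutoff or switching function is applied: the scan geometry is
a bare dimer at separations of a few Ångström, where truncation schemes
designed for condensed-phase simulation have no business.

Scans are generated by `build_approach_series()`: the molecule is held
rigid and the ion is placed at exact anchor–ion distances, by default 2 to
7 Å in 0.1 Å increments (51 configurations). The approach direction is a
convention that the original scan protocol leaves open; we place the ion
along the unit vector opposite the normalized sum of bond vectors from the
anchor sulfur to its covalent neighbours — a lone-pair-bisector
approximation that is reproducible, chemically sensible, and independent of
the analog's orientation in space. Whether the analog should relax at each
distance is equally open; we keep it rigid, and no test depends on the
internal geometry beyond the anchor-distance contract.

The analogs themselves (methylthioethane for methionine, methanethiol for
cysteine) are built from idealized internal coordinates (C–S 1.81 Å,
C–C 1.53 Å, C–H 1.09 Å, S–H 1.34 Å, near-tetrahedral angles) and ship both
as code (`analog_geometry()`) and as XYZ fixtures. Partial charges are
patterned on aliphatic-sulfide assignments and sum exactly to zero.

### Parameter files

The CHARMM dialect is preserved on disk — `NONBONDED` entries store
$-\varepsilon$ and $R_{\min}/2$; `NBFIX` entries store $-\varepsilon$ and
the *full* pair $R_{\min}$ — while the internal representation always keeps
well depths as positive magnitudes. This removes a classic sign-error
hazard at the cost of one explicit conversion at the I/O boundary, which is
round-trip tested bit-identically. A `CHARGES` section (molecule, atom,
charge) is our dialect extension: CHARMM proper keeps charges in topology
files, which would be disproportionate baggage for a dimer model.

## The synthetic reference model

A reference scan normally comes from correlated quantum chemistry. The
generator `make_reference_curve()` stands in for it with the minimal
physics that produces the right phenomenology:

$$E_\mathrm{ref}(r) = E_\mathrm{Coulomb}(r)
  + \varepsilon_0\left[\left(\tfrac{R_0}{r}\right)^{12}
  - 2\left(\tfrac{R_0}{r}\right)^{6}\right] - \frac{B}{r^4},$$

where the $-B/r^4$ term is the leading ion–induced-dipole (induction)
interaction — precisely the physics a fixed-charge force field lacks. Its
role here is structural, not quantitative: it guarantees that the reference
is *strictly deeper* than any fixed-charge curve with the same base
parameters, so the fitted override must absorb the difference, which is the
defining behaviour of an NBFIX correction. The demonstration defaults
($\varepsilon_0 = 6$ kcal/mol, $R_0 = 2.9$ Å, $B = 160$ kcal·Å⁴/mol) were
chosen once so that the demo curve's minimum falls near 2.8 Å — the
characteristic thioether–Na⁺ contact distance — and are not otherwise
calibrated to any published scan; no numbers were read off published
figures.

The polarized-charge generator (`make_polarized_charges()`) is likewise
qualitative: a sigmoidal transfer moves charge from the sulfur's
neighbours onto the sulfur as the ion approaches, conserving total charge
exactly. Its testable content is conservation and monotonicity, not
particular charge values, and it is deliberately uncalibrated.

## The fit

`nbfix_fit()` (or `grid_fit()` + `refine_fit()`) minimizes

$$\chi^2(\varepsilon, R_{\min}) = \sum_k w(r_k)\,
  \left[\tilde E_\mathrm{MM}(r_k) - \tilde E_\mathrm{ref}(r_k)\right]^2$$

where the tilde denotes curves shifted to zero at the largest scanned
distance (scans report the *change* in potential energy, so absolute
offsets are meaningless; `fit_objective(anchor = FALSE)` disables the shift
for diagnostics). Two weighting schemes exist:

- `uniform` — every point weight 1; used in tests because it makes
  recovery objectives exactly interpretable.
- `close_range` (default) — normalized Boltzmann weights
  $w(r) \propto \exp(-\tilde E_\mathrm{ref}(r)/kT)$ with $kT = 0.593$
  kcal/mol (room temperature). This concentrates the fit on the well
  region, which is what matters for a bound ion, and suppresses both the
  steep repulsive wall (irrelevant, and impossible for a 12-6 form to
  match anyway) and the flat tail.

The grid spans 5.0–14.0 kcal/mol and 2.7–2.8 Å — the conventional scan
ranges for this correction — at 0.1 kcal/mol × 0.01 Å resolution, fine
enough that parameters quoted at that precision are representable grid
points. Ties break deterministically toward the smallest well depth, then
the smallest $R_{\min}$ (minimal perturbation). Refinement is a
Nelder–Mead simplex started at the grid optimum, box-constrained to the
grid bounds ± one step (candidates outside score `Inf`), run twice in
succession with relative tolerance $10^{-12}$; the result never has a
worse objective than its seed. On references generated by the package's
own MM model, the grid stage recovers in-grid overrides with objective
below $10^{-9}$ and refinement recovers off-grid truths to much better
than $10^{-3}$ — the property-level substitute for refitting against
quantum-chemical data that cannot be regenerated at desk scale. The
packaged override shipped with the parameter files (well depth 13.4
kcal/mol, $R_{\min}$ 2.8 Å, `met_na_override()`) is a distributed default
of exactly this kind, not a quantity the package re-derives.

`curve_minimum()` locates well minima. The prescribed textbook estimator —
a parabola through the lowest point and its neighbours — carries a
systematic bias on asymmetric wells (≈ +0.012 Å for a 12-6 well sampled at
0.1 Å, because the repulsive wall is steeper than the attractive tail), so
for curves with at least five points the parabolic estimate is polished by
minimizing a cubic-spline interpolant over the bracketing interval. Coarse
three-point curves keep the exact parabola, which reproduces quadratic
data to machine precision. Boundary minima (monotone curves) are returned
verbatim with a `boundary` flag rather than an error.

## Structure mining

`scan_structure()` identifies Na⁺–sulfur contacts under the two standard
filters: recorded resolution at most 3.0 Å, and ion–sulfur distance at
most 3.5 Å, *inclusive*. Ions are `HETATM` records with residue name `NA`;
sulfurs are Met `SD` or Cys `SG`. Policy choices, each deterministic and
conventional:

- The deposited coordinates (first model) are scanned, not expanded
  biological assemblies: assembly expansion depends on generator metadata
  that varies across files, while the asymmetric unit is reproducible.
- Alternate locations keep the highest-occupancy conformer; ties go to
  altloc `A`. No occupancy or B-factor filters are applied.
- A structure without a recorded resolution is skipped with a logged
  warning rather than silently passed or fatally rejected; corpus scans
  (`scan_corpus()`) count such skips and continue past corrupt files.

Contact rows are reported per (ion, sulfur) pair without deduplicating
symmetry-equivalent chains; the per-structure summary lets the user
aggregate either way. `measure_site_distance()` reports per-chain minimum
ion–atom distances and their mean (rounded to 0.1 Å by default), the
statistic used to compare a scan minimum with a crystallographic site
distance averaged over protomers. The test suite exercises these scans
exclusively on synthetic fixture structures with constructed-truth
distances; validating against a particular deposited entry requires a
download and is left to the user.

## Stoichiometry and assay design

For a cycle moving species $i$ with stoichiometry $\nu_i$, charge $z_i$
and concentrations $c_{i,\mathrm{in}}, c_{i,\mathrm{out}}$, the reversal
potential (inside minus outside) is

$$V_\mathrm{rev} = -\frac{s}{z_\mathrm{net}} \sum_i \nu_i
  \log_{10}\frac{c_{i,\mathrm{in}}}{c_{i,\mathrm{out}}},
  \qquad z_\mathrm{net} = \sum_i \nu_i z_i.$$

The slope default is $s = 60$ mV/decade rather than the 25 °C value
59.16: assay designs in this field round the slope, and the canonical
designed potentials (−78.06, −39.03, −26.02 mV for net charges 1, 2, 3
under a 20-fold substrate gradient) equal $-60\log_{10}20/z_\mathrm{net}$
exactly. The slope is configurable. Only concentration *ratios* enter, so
units cancel per species; coefficients are positive for co-transport and
negative for antiport (supported for generality, unused here).

Flux direction follows the free energy of one forward (influx) cycle,
$\Delta G = z_\mathrm{net} F (V_\mathrm{applied} - V_\mathrm{rev})$:
negative drives influx, positive efflux, and potentials within 0.5 mV of
$V_\mathrm{rev}$ report equilibrium. Note the sign: a potential *more
negative* than $V_\mathrm{rev}$ drives the positively charged cycle
inward, uphill against the substrate gradient.

`k_diffusion_recipe()` inverts the Nernst relation for a valinomycin K⁺
diffusion potential: required external K⁺ is
$[\mathrm{K}]_\mathrm{in} \cdot 10^{V/s}$; added KCl is that requirement
minus the K⁺ carried over by diluting the proteoliposomes (20-fold
dilution of 50 mM internal K⁺ carries over exactly 2.5 mM — enough, on its
own, to set the −78 mV condition with zero added KCl); choline chloride
tops up a constant total added salt. Carryover defaults to zero because
the published recipe values for the two nonzero-KCl conditions are only
reproduced that way, while the zero-KCl condition requires accounting for
carryover — an inconsistency of about 0.1 mM in the source recipes that we
document rather than resolve. Recipes are rounded to 0.1 mM.

## Trajectory analysis

Distance series (`pair_distance_series()`, `nearest_distance_series()`,
`point_distance_series()`) are plain Euclidean distances — no
minimum-image convention. The distances of interest are intra-site (a few
Å) in simulation boxes two orders of magnitude larger, and the synthetic
fixtures are non-periodic; applying periodic imaging would be untestable
dead code here. This is a documented limitation for users importing
trajectories whose molecules are wrapped.

`detect_dissociation()` reports the earliest frame from which a series
stays above a threshold for a full dwell window, with an `irreversible`
flag when it never returns below threshold. The defaults — threshold 8 Å,
dwell 100 frames — are package choices, not literature values (the source
analyses report dissociation visually): 8 Å is well beyond any direct
coordination distance, and the dwell excludes transient excursions. Both
are configurable, and reports generated by the CLI label the defaults as
package choices. Histograms default to 0.1 Å bins (matching the scan
resolution used throughout), use half-open bins with the last bin closed,
and are density-normalized so that $\sum_k d_k \Delta_k = 1$ exactly.

`occupancy_grid()` optionally superposes each frame on a reference frame
by least-squares rigid-body fit (via `bio3d::fit.xyz`) over an alignment
selection — at least three non-collinear atoms, or the superposition is
refused as degenerate — then bins selected atoms into cubic voxels
(default 0.5 Å) and divides counts by the frame count. Pooling equivalent
subunits is done by running the grid once per subunit with per-subunit
alignment selections and summing counts; no automatic symmetry detection
is attempted. Before normalization the total count equals frames ×
selection size, which the tests assert as a conservation law.

## The trajectory generator

`make_synthetic_trajectory()` emulates the phenomenology the analyses must
detect, with controllable ground truth rather than physical dynamics:

- **Bound phase** — the ion fluctuates isotropically about the site center
  with per-axis standard deviation `bound_sigma` (default 0.5 Å, a typical
  magnitude for an ion in a coordination site). The radial distance then
  has mean $\sigma\sqrt{8/\pi}$ and standard deviation
  $\sigma\sqrt{3 - 8/\pi}$, closed forms the tests compare against.
- **Escape phase** — from the dissociation frame onward the ion performs a
  biased random walk: drift `escape_rate` (default 0.1 Å/frame) along a
  fixed random direction plus per-step jitter of 0.2·`bound_sigma`. The
  drift is deliberately fast relative to the bound fluctuation so that a
  5σ threshold with a 50-frame dwell recovers the true dissociation frame
  within about 60 frames — the generator models the *prompt, irreversible*
  unbinding seen when a binding site is mis-parameterized, not diffusive
  re-crossing kinetics.
- **Waters** fluctuate about fixed stations in a box around the site.

Identical seeds give bit-identical trajectories; the generator saves and
restores the global RNG state. What passing these tests shows is that the
analysis operations recover known truth from data with the right gross
features (bound fluctuation, timed escape, stationary solvent). What they
do not show is robustness to force-field artifacts absent from the
generator — re-binding events, anisotropic site fluctuation, correlated
solvent motion, periodic wrapping — which is why the generator's role is
verification of the analysis code, never evidence about real systems.

## Problem sizes and numerical conventions

The default test and acceptance runs use: 51-point scans; a 91 × 11 fit
grid (cached so each candidate costs one vector expression); simplex
refinement with relative tolerance $10^{-12}$ and up to 2 × 2000
iterations; synthetic trajectories of 600–5000 frames; 20 seeded
trajectories for the dissociation-recovery rate; and fixture corpora of
three structures. The full suite runs in a few seconds on one CPU. Energies
are kcal/mol, distances Å, times ns, potentials mV, concentrations mM (µM
where stated); ε is positive in memory and negative in files, everywhere.

## Known limitations

- The dimer model has no intramolecular terms; analogs are rigid, and the
  approach path is a convention (see above), so fitted overrides inherit
  that convention.
- The reference model's induction term is the leading-order stand-in for
  polarization; real reference scans have exchange-repulsion and
  charge-transfer contributions a 12-6-plus-$r^{-4}$ form cannot represent,
  which is why the close-range weighting matters.
- One override pair is fitted per run; simultaneous multi-pair fitting is
  out of scope (and unnecessary for a single corrected pair).
- Structure scanning reads deposited coordinates only; assembly expansion,
  live database queries and bulk downloading are out of scope.
- No free-energy, kinetics, or conformational-state classification is
  attempted from trajectories; the analyses are strictly geometric.
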