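---
title: "Methods: solvation analysis of disordered terminal tails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: solvation analysis of disordered terminal tails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

Many proteins carry long intrinsically disordered terminal tails whose
sequences are strikingly hydrophilic and low-complexity: rich in glycine,
proline, and charged residues such as arginine and lysine. `tailsolv`
quantifies what such tails do to a protein's solvation thermodynamics and
surface composition. The package computes four families of quantities:

1. **GB/SA hydration free energies** of a structure and of its truncation
   variants (tail-less core, N-terminally shortened), absolute and
   normalized per residue;
2. **solvent-accessible surface areas** (Shrake–Rupley), relative
   accessibilities against free-amino-acid references, and the share of
   the total surface contributed by the tails;
3. **sequence Shannon entropies** of "composite sequences" — the residues
   of a segment whose relative accessibility clears a cutoff — swept over
   cutoffs;
4. **ensemble structural statistics**: radius of gyration, Kabsch-superposed
   pairwise backbone RMSD per segment, per-frame series, and percentile
   placement of a query against a reference distribution.

A seeded synthetic-structure generator supplies globule-plus-tail
constructs and conformer ensembles so the whole pipeline runs and is
tested without any external data.

## The hydration free energy model

The solvation free energy is the implicit-solvent GB/SA form
$\Delta G = \Delta G_\text{pol} + \sigma \, A_\text{SASA}$.

The polar term is the generalized Born sum over all atom pairs
(including self-terms):

$$\Delta G_\text{pol} = -\tfrac12\left(\frac{1}{\epsilon_\text{in}} -
\frac{1}{\epsilon_\text{solv}}\right) k_C \sum_{i,j}
\frac{q_i q_j}{f_{ij}}, \qquad
f_{ij} = \sqrt{r_{ij}^2 + R_i R_j e^{-r_{ij}^2 / 4 R_i R_j}},$$

with $f_{ii} = R_i$. Effective Born radii $R_i$ come from
Hawkins–Cramer–Truhlar pairwise descreening integrals with the
Onufriev–Bashford–Case tanh correction (model II coefficients
$\alpha = 1.0$, $\beta = 0.8$, $\gamma = 4.85$; radius offset 0.09 Å). An
isolated atom has exactly $R = \rho - 0.09$ Å; burial increases $R$; radii
are clamped to never fall below the reduced intrinsic radius. Defaults:
$\epsilon_\text{in} = 1$, $\epsilon_\text{solv} = 78.5$,
$k_C = 332.0636$ kcal Å/(mol e²) converted once to kJ, surface tension
$\sigma = 0.0209$ kJ/(mol Å²) (0.005 kcal). All reported energies are in
kJ/mol; normalized energies in kJ/mol/residue. The double sum is evaluated
exactly by default (`cutoff = Inf`); a distance cutoff is available and is
required by the tests to agree with the exact path to within 0.1 %.

`transfer_scaling()` exposes the proportionality of the polar term to the
difference of inverse dielectric constants: a computed water-transfer
energy can be rescaled to any $\epsilon_a \to \epsilon_b$ transfer without
re-evaluating the Born sum.

### United heavy-atom parameterization

Structures are scored in **united heavy-atom** mode: hydrogens are not
required in the input, and each heavy atom's partial charge includes its
bonded hydrogens. The bundled plain-text parameter table
(`inst/extdata/gb_params.txt`) assigns every standard heavy atom a charge,
an intrinsic radius (per element: C 1.70, N 1.55, O 1.52, S 1.80 Å) and an
HCT screening scale (C 0.72, N 0.79, O 0.85, S 0.96). The charge set is a
deliberately simple monopole model — backbone N −0.28, CA +0.23, C +0.60,
O −0.55, side chains carrying chemically sensible dipoles — constrained so
that every residue's charges sum exactly to its integer formal charge (0
for neutral residues, −1 for Asp/Glu, +1 for Lys/Arg). Termini are charged
by default (+1 collapsed onto the N-terminal nitrogen; −1 spread over the
carboxylate oxygens), switchable to neutral caps.

This is coarser than an all-atom force-field charge set, and absolute
energies are therefore not comparable to all-atom GB/SA numbers. The
package's analysis surface — orderings between full, truncated and
core-only structures, surface fractions, percentile placements — depends
on monopole-level electrostatics, which the parameterization preserves.

## Surface areas and relative accessibility

SASA uses the Shrake–Rupley construction: 960 golden-spiral quadrature
points per atom on the sphere of radius $r_\text{vdW} + 1.4$ Å, a point
being accessible when it lies outside every neighbour's expanded sphere.
The choice of a deterministic spiral makes results reproducible to the
bit; quadrature error against a 4000-point evaluation is bounded at 2 % in
the tests and against a Monte-Carlo estimate at 3 standard errors.
Hydrogens are ignored (consistent with the united-atom energy model).

Relative accessibility divides a residue's SASA in the structure by the
SASA of the *free* amino acid — a single residue with terminal OXT in the
package's extended template geometry, computed with the same engine and
settings and cached. Values are deliberately **not capped at 1**; unusual
conformations may slightly exceed the extended-template reference, and
cutoff logic is unaffected. The conventional surface-residue cutoff is
0.4; a cutoff of 0 selects every residue.

## Composite sequences and Shannon entropy

For a segment and cutoff, the composite sequence collects the one-letter
codes of residues at or above the cutoff; order is irrelevant by
construction. Entropy is $H = -\sum_i p_i \ln p_i$ over the amino-acid
frequencies. The **natural logarithm** is used: the entropy of a uniform
20-letter composition is $\ln 20 \approx 2.996$, which matches the
converged surface-composition value around 3.0 that motivates the
analysis; a base-2 convention (maximum 4.32) would not. Ensemble
statistics are computed per model first and then averaged (mean ± sample
SD); empty composites become missing values, flagged and excluded from
means with a warning rather than dropped silently.

## Ensemble descriptors

Backbone RMSD uses the four-atom backbone convention (N, CA, C, O) and a
proper-rotation Kabsch superposition; per-segment RMSD superposes **on the
segment itself** (tails fitted on tails, cores on cores), which is the
convention that makes tail diversity visible rather than inflating it
with core motion. Radius of gyration is mass-weighted over heavy atoms
with a documented uniform-weight switch. All spreads are sample (n−1)
standard deviations. Percentile placement of a query against a reference
distribution counts values *strictly* more positive; ties count against
the query.

## The reference-set filters

`passes_filters()` implements the mechanical predicates used to assemble
a representative background set of high-quality structures: X-ray method,
resolution ≤ 2.5 Å, R-factor ≤ 0.3 (treated as dimensionless), length
≥ 40 residues, no chain breaks, no nonstandard residues, all side chains
resolved, and none of mutant/complexed/fragment/membrane. Flags that
coordinates cannot decide (side-chain completeness, membrane annotation)
are caller-supplied metadata — an honest scoping choice. Chain breaks are
detected from coordinates as Cα–Cα gaps above 4.5 Å (the conventional
trans-peptide bound) or residue-numbering jumps. Manual curation of
borderline entries and pre-scoring energy minimization are out of scope;
inputs are scored as-is.

## What the synthetic generator emulates — and what it does not

The generator produces, from an explicit seed, constructs with the
statistical structure the analysis assumes:

* a **compact core** of typical globular composition whose radius of
  gyration follows the globular scaling $R_g \approx 2.2\,N^{0.38}$ Å
  (enforced within ±28 %), with hydrophobic side chains biased inward and
  hydrophilic ones outward;
* **low-complexity hydrophilic tails** (default composition G 0.20,
  P 0.10, R 0.175, K 0.175, S 0.10, E 0.10, Q 0.05, D 0.05, N 0.05;
  composition entropy ≈ 2.07 versus ≈ 2.94 for the core background) in
  extended or collapsed conformation, default lengths 80 (N) and 40 (C)
  around a 150-residue core;
* **conformer ensembles** in which the core is jittered mildly
  (default 0.5 Å Gaussian) while tails are re-sampled from scratch with
  the same sequence — high tail diversity around a stable core.

Geometry is deliberately coarse: residues are placed on a self-avoiding
trace (step 4.0 Å, non-adjacent separation ≥ 4.2 Å) grown together with
clash-checked orientations of an idealized heavy-atom template whose
spacings are inflated so that **no atom pair is closer than 2.0 Å**.
There is no Ramachandran sampling, no secondary structure, no covalent
bond lengths. Globule generation additionally verifies that both chain
termini remain solvent-exposed enough to host a tail's first residue
(probed with a bulky template) — physically, tail-bearing termini are
exposed, and computationally this keeps tail attachment fast for every
seed. Consequently, passing tests demonstrate that the *methods*
respond correctly to composition, compactness and burial — the properties
the generator controls — not that the package reproduces any particular
real protein's absolute energies. Clash-free construction is attempted
within bounded retries (orientation candidates, chain backtracking, up to
60 restarts) and fails loudly with reseeding advice rather than returning
a defective structure.

## Numerical choices and degenerate inputs

* Altloc resolution on read: highest occupancy wins, ties to the
  alphabetically first label.
* Overlapping identical coordinates are a geometry error for the Born
  radius machinery; zero-charge atoms short-circuit the pair sum.
* Kabsch superposition requires ≥ 3 non-collinear atoms; collinear
  selections raise a degenerate-geometry error.
* A single-value distribution reports SD 0 with an explicit
  `sd_defined = FALSE` flag.
* Segment indices are 1-based and inclusive; truncation preserves the
  surviving residues' original numbering so segment arithmetic composes
  (`truncate(a)` then `truncate(b)` equals `truncate(a+b)`).
* Dimer-style analyses are supported by per-chain segments; whether tails
  are defined on one or both protomers is configuration, not hard-coded.

## Problem sizes used by the tests

The test-suite and acceptance script sizes were chosen as the smallest
that exercise each property honestly: unit fixtures use 12–65-residue
constructs; direction-of-effect checks use 20 independent replicates at
the full default geometry (150-residue core, 80+40-residue tails,
~2100 heavy atoms each); the synthetic reference set uses 30 tail-less
globules of 60–180 residues; ensemble statistics use 12 conformers. The
oracle suite compares Shrake–Rupley areas against Monte-Carlo sampling on
20 random atom clusters, the descreening integral against a 4·10⁵-point
volume integral, and the GB pair sum against a cutoff-accelerated path on
a ~500-atom globule.

## Known limitations

* Absolute hydration free energies are on the united-atom charge scale
  and are systematically more negative per residue than all-atom GB/SA
  values; only orderings, fractions and percentiles should be compared
  across parameterizations.
* SASA rotation invariance is exact only up to quadrature (the spiral is
  fixed in the laboratory frame); the tests bound the effect at well
  under 1 %.
* The generator's conformers are not a thermodynamic ensemble; time-series
  utilities treat frames as labels, not dynamics.
* DSSP-style accessibility conventions differ in detail from
  Shrake–Rupley; systematic small differences in relative accessibility
  are expected and accepted.
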