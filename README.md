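# tailsolv

Solvation analysis of proteins with intrinsically disordered terminal
tails.

Long disordered N- and C-terminal tails are common in extremophile
proteomes and are strikingly hydrophilic and low-complexity — rich in
glycine, proline, arginine and lysine. `tailsolv` is an R package for
asking, quantitatively, what such tails do to a protein's solvation: how
much hydration free energy they contribute, how much of the molecular
surface they provide, how their sequence complexity compares with the
solvent-exposed surface of an ordered core, and how structurally diverse
they are across a conformational ensemble.

## What it computes

**Hydration free energy (GB/SA).** The implicit-solvent form
ΔG = ΔG_pol + σ·A_SASA. The polar term is the generalized Born double sum

    ΔG_pol = −½ (1/ε_in − 1/ε_solv) k_C Σ_ij q_i q_j / f_GB(r_ij, R_i, R_j),
    f_GB  = sqrt(r² + R_i R_j exp(−r²/(4 R_i R_j))),

with effective Born radii R_i from Hawkins–Cramer–Truhlar pairwise
descreening plus the Onufriev–Bashford–Case tanh correction (OBC II:
α = 1.0, β = 0.8, γ = 4.85, offset 0.09 Å). The nonpolar term is a
surface tension (0.0209 kJ mol⁻¹ Å⁻²) times the Shrake–Rupley
solvent-accessible surface area. Energies are reported absolute (kJ/mol)
and size-normalized (kJ/mol/residue) for full, N-terminally truncated,
and core-only variants of a structure.

**Surface accessibility.** Shrake–Rupley SASA on a 960-point golden
spiral; per-residue relative accessibility against the free amino acid;
surface-residue selection at a cutoff (0.4 conventional); segment SASA
fractions.

**Sequence Shannon entropy.** H = −Σ p_i ln p_i of "composite sequences"
— the residues of a tail, core, or whole chain whose relative
accessibility clears a cutoff — swept over cutoffs, per model and
ensemble-averaged.

**Ensemble statistics.** Radius of gyration, Kabsch-superposed pairwise
backbone RMSD per segment, per-frame series, reference distributions with
percentile placement of a query.

**Reference-set filters.** The mechanical predicates for assembling a
representative background set (X-ray, resolution ≤ 2.5 Å, R ≤ 0.3,
≥ 40 residues, no chain breaks/nonstandard residues, exclusion flags),
plus coordinate-based chain-break detection.

**Synthetic data.** A fully seeded generator of compact globules with
hydrophilic low-complexity tails and of conformer ensembles, so the whole
pipeline runs and is tested without external structures.

## Worked example

```r
library(tailsolv)

cfg  <- generator_config(seed = 42, core_length = 60, tail_lengths = c(20, 10))
full <- attach_tails(generate_globule(cfg), cfg)
segs <- attr(full, "segments")
core <- extract_segment(full, segs[segs$name == "core", ])

dplyr::bind_rows(
  hydration_free_energy(full, label = "full"),
  hydration_free_energy(core, label = "core"))
#> # A tibble: 2 × 7
#>   label model   polar nonpolar   total normalized n_residues
#>   <chr> <int>   <dbl>    <dbl>   <dbl>      <dbl>      <int>
#> 1 full      1 -19638.     234. -19404.      -216.         90
#> 2 core      1 -10359.     134. -10226.      -170.         60

tab <- relative_accessibility(residue_sasa(full))
entropy_sweep(tab, segs, cutoffs = c(0, 0.2, 0.4))
#> # A tibble: 9 × 5
#>   segment cutoff n_residues entropy empty
#>   <chr>    <dbl>      <int>   <dbl> <lgl>
#> 1 ntail      0           20    2.07 FALSE
#> 2 ntail      0.2         19    1.97 FALSE
#> 3 ntail      0.4         15    1.99 FALSE
#> 4 core       0           60    2.87 FALSE
#> 5 core       0.2         38    2.67 FALSE
#> 6 core       0.4         20    2.35 FALSE
#> 7 ctail      0           10    1.47 FALSE
#> 8 ctail      0.2         10    1.47 FALSE
#> 9 ctail      0.4          9    1.43 FALSE

sasa_fraction(full, segs[segs$name != "core", ])
#> [1] 46.09736
```

Read the numbers this way: the tailed construct is far more favourably
hydrated *per residue* (−216 vs −170 kJ/mol/residue) because the tails
are essentially all surface and heavily charged; the tails' sequence
entropy (≈ 2.1 and below) sits well under the core's (≈ 2.9 ≈ ln 20 for
near-uniform composition), and the gap narrows as the cutoff restricts
the core to its own solvent-exposed — hydrophilic — residues; and two
tails holding a third of the residues supply ~46 % of the whole surface.
`run_full_analysis()` produces all of these tables (plus per-frame Rg and
SASA series, per-segment pairwise RMSDs, and a reference-distribution
percentile) in one call over an ensemble.

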