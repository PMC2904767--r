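Package: tailsolv
Title: Solvation Analysis of Proteins with Intrinsically Disordered Terminal Tails
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how intrinsically disordered terminal tails
    change a protein's solvation properties. Computes implicit-solvent
    hydration free energies with a generalized Born (OBC) polar term plus a
    surface-area nonpolar term, Shrake-Rupley solvent-accessible surface
    areas and relative accessibilities, accessibility-stratified sequence
    Shannon entropies, and ensemble structural statistics (radius of
    gyration, Kabsch-superposed backbone RMSD, distribution and percentile
    summaries). Includes reference-set filter predicates for assembling
    background distributions and a seeded generator of synthetic globule-
    plus-tail structures and ensembles so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
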