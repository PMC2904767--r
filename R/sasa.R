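# Solvent-accessible surface area: Shrake-Rupley quadrature over
# golden-spiral sphere points, per-residue aggregation, relative
# accessibility against free-amino-acid references, surface-residue
# selection, and segment SASA fractions.

#' Settings for surface-area calculations
#'
#' @param probe_radius Solvent probe radius in Angstrom (1.4, water).
#' @param n_sphere_points Number of quadrature points per atom (golden
#'   spiral); at least 92.
#' @param radius_table Named van der Waals radii per element, Angstrom.
#' @return List of class `sasa_settings`.
#' @export
sasa_settings <- function(probe_radius = 1.4,
                          n_sphere_points = 960,
                          radius_table = c(C = 1.70, N = 1.55, O = 1.52,
                                           S = 1.80, H = 1.20)) {
  stopifnot(probe_radius > 0, n_sphere_points >= 92)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radius_table = radius_table),
            class = "sasa_settings")
}

# Van der Waals radii for the heavy atoms of one model; errors name the
# offending atom.
#' @keywords internal
atom_radii <- function(m, settings) {
  r <- settings$radius_table[m$element]
  if (anyNA(r)) {
    bad <- m[is.na(r), ][1, ]
    abort(paste0("no van der Waals radius for atom ", bad$elety,
                 " (element ", bad$element, ") in ", bad$resid, " ",
                 bad$resindex),
          class = "tailsolv_parameterization_error")
  }
  unname(r)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe of radius `probe_radius` over the van der Waals spheres of
#' the heavy atoms; each atom's accessible area is the fraction of
#' quadrature points on its expanded sphere not buried inside any
#' neighbour's expanded sphere. Hydrogens are ignored.
#'
#' @param x Atom tibble (single model).
#' @param settings [sasa_settings()].
#' @return The heavy-atom tibble with an added `area` column (Angstrom^2).
#' @export
shrake_rupley <- function(x, settings = sasa_settings()) {
  m <- one_model(x)
  m <- m[m$element != "H", , drop = FALSE]
  if (nrow(m) == 0) {
    abort("no heavy atoms in structure", class = "tailsolv_input_error")
  }
  r <- atom_radii(m, settings)
  m$area <- as.numeric(sasa_atoms_cpp(coord_matrix(m, heavy = FALSE), r,
                                      settings$probe_radius,
                                      settings$n_sphere_points))
  m
}

#' Per-residue absolute solvent accessibility
#'
#' @param x Atom tibble (single model).
#' @param settings [sasa_settings()].
#' @return Accessibility table: one row per residue with `chain`,
#'   `resindex`, `resno`, `resid`, `code1` and `abs_sa` (Angstrom^2).
#' @export
residue_sasa <- function(x, settings = sasa_settings()) {
  at <- shrake_rupley(x, settings)
  out <- at %>%
    group_by(.data$chain, .data$resindex, .data$resno, .data$resid) %>%
    summarise(abs_sa = sum(.data$area), .groups = "drop")
  out$code1 <- unname(AA_THREE_TO_ONE[out$resid])
  out[order(match(out$chain, unique(at$chain)), out$resindex), ]
}

#' Reference surface areas of free amino acids
#'
#' SASA of each isolated amino acid in the package's extended template
#' conformation, computed with the same engine and settings as every other
#' surface calculation and cached per settings. These are the denominators
#' of relative solvent accessibility.
#'
#' @param settings [sasa_settings()].
#' @return Tibble with `code1`, `code3`, `max_sa` (20 rows).
#' @export
max_sa_reference <- function(settings = sasa_settings()) {
  key <- rlang::hash(settings)
  hit <- .tailsolv_cache[[key]]
  if (!is.null(hit)) return(hit)
  codes <- names(AA_SIDE_ATOMS)
  vals <- vapply(codes, function(c3) {
    sum(shrake_rupley(free_residue(c3), settings)$area)
  }, numeric(1))
  out <- tibble(code1 = unname(AA_THREE_TO_ONE[codes]), code3 = codes,
                max_sa = unname(vals))
  .tailsolv_cache[[key]] <- out
  out
}

#' Fill the relative-accessibility column
#'
#' Relative accessibility is the residue's absolute SASA divided by the
#' SASA of the free amino acid of the same type. Values are deliberately
#' not capped at 1: residues in unusual conformations may slightly exceed
#' the extended-template reference.
#'
#' @param table Accessibility table from [residue_sasa()].
#' @param ref Reference table from [max_sa_reference()].
#' @return `table` with an added `rel_sa` column.
#' @export
relative_accessibility <- function(table, ref = max_sa_reference()) {
  mx <- ref$max_sa[match(table$code1, ref$code1)]
  if (anyNA(mx)) {
    bad <- unique(table$resid[is.na(mx)])
    abort(paste0("no reference surface area for residue(s): ",
                 paste(bad, collapse = ", ")),
          class = "tailsolv_parameterization_error")
  }
  table$rel_sa <- table$abs_sa / mx
  table
}

#' Select surface residues at an accessibility cutoff
#'
#' Residues whose relative accessibility is at least `cutoff`. A cutoff of
#' 0 keeps every residue, buried and exposed alike; 0.4 is the
#' conventional literature definition of a surface residue.
#'
#' @param table Accessibility table with the `rel_sa` column filled.
#' @param cutoff Relative-accessibility threshold (>= 0).
#' @return The rows of `table` passing the cutoff.
#' @export
surface_residues <- function(table, cutoff) {
  stopifnot(cutoff >= 0, "rel_sa" %in% names(table))
  table[table$rel_sa >= cutoff, , drop = FALSE]
}

#' Fraction of total surface area contributed by segments
#'
#' Sum of the segment residues' SASA in the intact structure, as a
#' percentage of the structure's total SASA. Quantifies e.g. how much of a
#' protein's accessible surface its disordered tails provide.
#'
#' @param x Atom tibble (single model).
#' @param segs Segment tibble (zero or more rows).
#' @param settings [sasa_settings()].
#' @return Percentage in `[0, 100]`.
#' @export
sasa_fraction <- function(x, segs, settings = sasa_settings()) {
  tab <- residue_sasa(x, settings)
  total <- sum(tab$abs_sa)
  if (total <= 0) return(0)
  in_seg <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(segs))) {
    in_seg <- in_seg | (tab$chain == segs$chain[i] &
                          tab$resindex >= segs$first[i] &
                          tab$resindex <= segs$last[i])
  }
  100 * sum(tab$abs_sa[in_seg]) / total
}
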