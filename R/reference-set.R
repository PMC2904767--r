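# Reference-set assembly: the mechanical filter predicates used to build
# a representative set of high-quality X-ray structures, chain-break
# detection, and the normalized-HFE background distribution.

#' Apply reference-set filters to structure metadata
#'
#' Accepts a structure iff it is an X-ray structure with resolution
#' <= 2.5 A, R-factor <= 0.3, at least 40 residues, no chain breaks, no
#' nonstandard residues, all side chains resolved, and none of the
#' exclusion flags (mutant, complexed, fragment, membrane) set. Every
#' failed predicate is reported as a reason.
#'
#' @param meta Tibble with columns `id`, `method`, `resolution`,
#'   `r_factor`, `length`, `has_chain_breaks`, `has_nonstandard`,
#'   `all_side_chains_resolved`, `is_mutant`, `is_complexed`,
#'   `is_fragment`, `is_membrane`.
#' @param max_resolution,max_r_factor,min_length Filter thresholds.
#' @return `meta` with added `accept` (logical) and `reasons` (character,
#'   semicolon-separated failed predicates, empty when accepted).
#' @export
passes_filters <- function(meta, max_resolution = 2.5, max_r_factor = 0.3,
                           min_length = 40) {
  need <- c("id", "method", "resolution", "r_factor", "length",
            "has_chain_breaks", "has_nonstandard",
            "all_side_chains_resolved", "is_mutant", "is_complexed",
            "is_fragment", "is_membrane")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("metadata lacks field(s): ", paste(missing, collapse = ", ")),
          class = "tailsolv_metadata_error")
  }
  if (anyNA(meta[need])) {
    abort("metadata contains missing values in mandatory fields",
          class = "tailsolv_metadata_error")
  }
  checks <- list(
    method = meta$method == "X-ray",
    resolution = meta$resolution <= max_resolution,
    r_factor = meta$r_factor <= max_r_factor,
    length = meta$length >= min_length,
    chain_breaks = !meta$has_chain_breaks,
    nonstandard = !meta$has_nonstandard,
    side_chains = meta$all_side_chains_resolved,
    mutant = !meta$is_mutant,
    complexed = !meta$is_complexed,
    fragment = !meta$is_fragment,
    membrane = !meta$is_membrane
  )
  ok <- Reduce(`&`, checks)
  reasons <- vapply(seq_len(nrow(meta)), function(i) {
    paste(names(checks)[!vapply(checks, `[`, logical(1), i)],
          collapse = ";")
  }, character(1))
  meta$accept <- ok
  meta$reasons <- reasons
  meta
}

#' Detect chain breaks from coordinates
#'
#' A break is flagged between consecutive residues of a chain when the
#' CA-CA distance exceeds `max_ca_gap` (4.5 A, the conventional
#' trans-peptide bound) or the residue numbering jumps.
#'
#' @param x Atom tibble (single model) with CA atoms present.
#' @param max_ca_gap Distance threshold in Angstrom.
#' @return Tibble of breaks: `chain`, `after_resindex`, `ca_gap`,
#'   `numbering_gap`.
#' @export
detect_chain_breaks <- function(x, max_ca_gap = 4.5) {
  m <- one_model(x)
  ca <- m[m$elety == "CA", , drop = FALSE]
  out <- list()
  for (ch in unique(m$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    cc <- cc[order(cc$resindex), , drop = FALSE]
    res_all <- unique(m$resindex[m$chain == ch])
    if (nrow(cc) < length(res_all)) {
      abort(paste0("missing CA atom(s) in chain ", ch),
            class = "tailsolv_geometry_error")
    }
    if (nrow(cc) < 2) next
    d <- sqrt(rowSums((as.matrix(cc[-1, c("x", "y", "z")]) -
                         as.matrix(cc[-nrow(cc), c("x", "y", "z")]))^2))
    gap <- diff(cc$resno) != 1L
    brk <- d > max_ca_gap | gap
    if (any(brk)) {
      out[[ch]] <- tibble(chain = ch,
                          after_resindex = cc$resindex[-nrow(cc)][brk],
                          ca_gap = d[brk], numbering_gap = gap[brk])
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(chain = character(), after_resindex = integer(),
           ca_gap = numeric(), numbering_gap = logical())
}

#' Build a reference distribution of normalized hydration free energies
#'
#' Scores each structure with [hydration_free_energy()] and collects the
#' size-normalized totals into a [ref_distribution()] for percentile and
#' summary queries.
#'
#' @param models List of single-model atom tibbles.
#' @param params,settings,sasa_settings Passed to
#'   [hydration_free_energy()].
#' @param labels Optional labels (defaults to list names or indices).
#' @return A `ref_distribution` of kJ/mol/residue values.
#' @export
build_reference_distribution <- function(models,
                                         params = default_parameter_set(),
                                         settings = gbsa_settings(),
                                         sasa_settings =
                                           tailsolv::sasa_settings(),
                                         labels = NULL) {
  if (length(models) == 0) {
    abort("empty reference set", class = "tailsolv_input_error")
  }
  if (is.null(labels)) {
    labels <- names(models)
    if (is.null(labels)) labels <- as.character(seq_along(models))
  }
  vals <- vapply(models, function(m) {
    hydration_free_energy(m, params, settings, sasa_settings)$normalized
  }, numeric(1))
  ref_distribution(vals, labels)
}
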