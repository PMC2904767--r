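# Structure slicing: segment vocabulary (N-tail / core / C-tail),
# extraction, N-terminal truncation, and sequence recovery.

#' Define a residue segment
#'
#' A segment names an inclusive 1-based residue-index range on one chain.
#' Segments are the vocabulary for tails and cores: e.g. an 80-residue
#' N-terminal tail on chain A is `segment("ntail", "A", 1, 80)`.
#'
#' @param name Segment label.
#' @param chain Chain identifier.
#' @param first,last First and last residue index (1-based, inclusive,
#'   referring to the `resindex` column).
#' @return One-row tibble with columns `name`, `chain`, `first`, `last`.
#' @export
segment <- function(name, chain, first, last) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first < 1L || first > last) {
    abort("segment requires 1 <= first <= last",
          class = "tailsolv_range_error")
  }
  tibble(name = name, chain = chain, first = first, last = last)
}

#' Extract a segment from a structure
#'
#' Returns the atoms of residues `first..last` of the segment's chain, for
#' every model present. Residue indices and numbers are preserved, so
#' segment arithmetic stays valid after extraction.
#'
#' @param x Atom tibble.
#' @param seg Segment tibble (one or more rows); rows are unioned.
#' @return Atom tibble restricted to the segment residues.
#' @export
extract_segment <- function(x, seg) {
  keep <- rep(FALSE, nrow(x))
  for (i in seq_len(nrow(seg))) {
    ch <- seg$chain[i]
    in_ch <- x$chain == ch
    if (!any(in_ch)) {
      abort(paste0("segment chain not present: ", ch),
            class = "tailsolv_range_error")
    }
    if (seg$last[i] > max(x$resindex[in_ch])) {
      abort(paste0("segment [", seg$first[i], ",", seg$last[i],
                   "] out of range for chain ", ch),
            class = "tailsolv_range_error")
    }
    keep <- keep | (in_ch & x$resindex >= seg$first[i] &
                      x$resindex <= seg$last[i])
  }
  x[keep, , drop = FALSE]
}

#' Complement of a segment set on a structure
#'
#' Residues of the structure not covered by any of the given segments.
#' @param x Atom tibble.
#' @param seg Segment tibble.
#' @return Atom tibble of the uncovered residues.
#' @export
segment_complement <- function(x, seg) {
  keep <- rep(TRUE, nrow(x))
  for (i in seq_len(nrow(seg))) {
    keep <- keep & !(x$chain == seg$chain[i] &
                       x$resindex >= seg$first[i] &
                       x$resindex <= seg$last[i])
  }
  x[keep, , drop = FALSE]
}

#' Remove the first k residues of a chain
#'
#' Deletes the k N-terminal residues (by residue index) of each designated
#' chain. Surviving residues keep their original numbering and
#' coordinates, mirroring how truncation variants of a modelled structure
#' are built for hydration-energy comparisons.
#'
#' @param x Atom tibble.
#' @param k Number of residues to remove (`0 <= k <` chain length).
#' @param chains Chains to truncate; default all chains.
#' @return Truncated atom tibble.
#' @export
truncate_n_terminal <- function(x, k, chains = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) {
    abort("k must be a non-negative integer", class = "tailsolv_range_error")
  }
  if (is.null(chains)) chains <- unique(x$chain)
  keep <- rep(TRUE, nrow(x))
  for (ch in chains) {
    in_ch <- x$chain == ch
    idx <- sort(unique(x$resindex[in_ch]))
    if (k >= length(idx)) {
      abort(paste0("k = ", k, " >= chain ", ch, " length ", length(idx)),
            class = "tailsolv_range_error")
    }
    if (k > 0L) keep <- keep & !(in_ch & x$resindex %in% idx[seq_len(k)])
  }
  x[keep, , drop = FALSE]
}

#' One-letter sequence of a structure
#'
#' @param x Atom tibble (single model, or the first model of an ensemble).
#' @return One-letter amino-acid string, chains concatenated in order of
#'   appearance, residues by index.
#' @export
sequence_of <- function(x) {
  m <- x[x$model == x$model[1], , drop = FALSE]
  res <- dplyr::distinct(m, .data$chain, .data$resindex, .data$resid)
  res <- res[order(match(res$chain, unique(m$chain)), res$resindex), ]
  one <- AA_THREE_TO_ONE[res$resid]
  if (anyNA(one)) {
    bad <- unique(res$resid[is.na(one)])
    abort(paste0("nonstandard residue(s): ", paste(bad, collapse = ", ")),
          class = "tailsolv_unsupported_residue_error")
  }
  paste(one, collapse = "")
}

#' Residue-level view of a structure
#'
#' @param x Atom tibble (one model).
#' @return Tibble with one row per residue: `chain`, `resindex`, `resno`,
#'   `resid`, `code1`.
#' @export
residue_table <- function(x) {
  m <- one_model(x)
  res <- dplyr::distinct(m, .data$chain, .data$resindex, .data$resno,
                         .data$resid)
  res <- res[order(match(res$chain, unique(m$chain)), res$resindex), ]
  res$code1 <- unname(AA_THREE_TO_ONE[res$resid])
  as_tibble(res)
}

#' Number of residues in a structure
#' @param x Atom tibble (models assumed to share one sequence).
#' @return Integer residue count of one model.
#' @export
n_residues <- function(x) {
  m <- x[x$model == x$model[1], , drop = FALSE]
  nrow(dplyr::distinct(m, .data$chain, .data$resindex))
}

# Coordinate matrix (n x 3) of one model, optionally heavy atoms only.
#' @keywords internal
coord_matrix <- function(x, heavy = TRUE) {
  if (heavy) x <- x[x$element != "H", , drop = FALSE]
  as.matrix(x[, c("x", "y", "z")])
}
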