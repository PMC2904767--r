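# PDB reading/writing. Parsing is delegated to bio3d; this layer reshapes
# multi-model files into the long atom tibble the rest of the package
# consumes, resolves alternate locations, and drops heteroatoms/waters.

#' Read a PDB file into an atom tibble
#'
#' Reads single- or multi-model PDB files. Each `MODEL`/`ENDMDL` block
#' becomes one value of the `model` column (a single block, or none, gives
#' `model == 1` throughout). HETATM records and waters are skipped.
#' Alternate locations are resolved to the highest-occupancy copy, ties
#' broken by the alphabetically first altloc label.
#'
#' @param path Path to a PDB file.
#' @return A tibble with one row per atom and columns `model`, `chain`,
#'   `resindex` (1-based position of the residue within its chain),
#'   `resno` (author residue number), `resid` (three-letter code), `elety`
#'   (atom name), `element`, and coordinates `x`, `y`, `z` in Angstrom.
#' @examples
#' pdb <- write_pdb(synthetic_globule_demo(), tempfile(fileext = ".pdb"))
#' head(read_pdb(pdb))
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read PDB file: ", path), class = "tailsolv_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) abort(
      paste0("failed to parse PDB file ", path, ": ", conditionMessage(e)),
      class = "tailsolv_io_error"
    )
  )
  at <- pdb$atom
  keep <- at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD"))
  if (!any(keep)) {
    abort(paste0("no standard ATOM records in ", path),
          class = "tailsolv_empty_structure_error")
  }
  at <- at[keep, , drop = FALSE]
  idx <- which(keep)

  # resolve altlocs: highest occupancy wins, ties to first altloc label
  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, ins, at$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  sel <- ord[!duplicated(key[ord])]
  sel <- sort(sel)
  at <- at[sel, , drop = FALSE]
  idx <- idx[sel]
  ins <- ins[sel]

  chain <- ifelse(is.na(at$chain), "A", at$chain)
  reskey <- paste(chain, at$resno, ins, sep = "\r")
  # residue index: order of first appearance within each chain
  resindex <- integer(nrow(at))
  for (ch in unique(chain)) {
    in_ch <- chain == ch
    resindex[in_ch] <- match(reskey[in_ch], unique(reskey[in_ch]))
  }

  element <- at$elesy
  bad <- is.na(element) | !(element %in% c("C", "N", "O", "S", "H"))
  element[bad] <- element_from_name(at$elety[bad])

  n_models <- nrow(pdb$xyz)
  cols <- as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx))
  out <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE)
    tibble(
      model = m, chain = chain, resindex = resindex,
      resno = at$resno, insert = ins, resid = at$resid,
      elety = at$elety, element = element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  })
  bind_rows(out)
}

#' Write an atom tibble to a PDB file
#'
#' Writes standard fixed-column ATOM records, coordinates to three
#' decimals. Inputs with more than one value of `model` produce a
#' multi-model file with `MODEL`/`ENDMDL` blocks.
#'
#' @param x Atom tibble as returned by [read_pdb()] or the synthetic
#'   generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(nrow(x) > 0)
  models <- split_models(x)
  m1 <- models[[1]]
  nat <- nrow(m1)
  xyz <- do.call(rbind, lapply(models, function(m) {
    if (nrow(m) != nat) {
      abort("all models must share identical atoms to be written",
            class = "tailsolv_io_error")
    }
    as.vector(t(as.matrix(m[, c("x", "y", "z")])))
  }))
  ok <- tryCatch({
    bio3d::write.pdb(
      file = path, xyz = xyz,
      resno = m1$resno, resid = m1$resid, eleno = seq_len(nat),
      elety = m1$elety, chain = m1$chain, elesy = m1$element,
      o = rep(1, nat), b = rep(0, nat)
    )
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) {
    abort(paste0("cannot write PDB file: ", path), class = "tailsolv_io_error")
  }
  invisible(path)
}

# Split an atom tibble into a list of single-model tibbles.
#' @keywords internal
split_models <- function(x) {
  if (!"model" %in% names(x)) return(list(x))
  lapply(split(x, x$model), identity)
}

# Assert the input holds exactly one model and return it.
#' @keywords internal
one_model <- function(x) {
  if ("model" %in% names(x) && length(unique(x$model)) > 1) {
    abort("expected a single-model structure; got an ensemble",
          class = "tailsolv_input_error")
  }
  x
}
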