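# Coarse idealized residue geometry. Every residue is built from the same
# local template: backbone N/CA/C/O plus a two-column "ladder" of
# side-chain heavy atoms extending along the side-chain direction. Bond
# spacings are inflated to ~2 Angstrom so that generated structures
# satisfy a global 2.0 A minimum interatomic distance; the geometry is
# deliberately schematic (composition, compactness class and
# clash-freedom are what the downstream analyses consume, not covalent
# detail).

# Local-frame template offsets; frame columns are (side, lateral, chain).
#' @keywords internal
residue_template_offsets <- function(code3, with_oxt = FALSE) {
  side <- AA_SIDE_ATOMS[[code3]]
  if (is.null(side)) {
    abort(paste0("no template for residue ", code3),
          class = "tailsolv_unsupported_residue_error")
  }
  name <- c("N", "CA", "C", "O", side)
  off <- rbind(
    N  = c(0, -1.25, -1.65),
    CA = c(0, 0, 0),
    C  = c(0, -1.25, 1.65),
    O  = c(0, -3.10, 2.58)
  )
  if (length(side)) {
    k <- seq_along(side)
    off <- rbind(off, cbind(2.05 + 2.05 * floor((k - 1) / 2),
                            ifelse(k %% 2 == 1, 1.1, -1.1),
                            0))
  }
  if (with_oxt) {
    name <- c(name, "OXT")
    off <- rbind(off, c(0, -1.25, 3.72))
  }
  rownames(off) <- NULL
  list(name = name, offsets = off)
}

# Place a residue template at a CA position with an orthonormal frame.
# frame: 3x3 matrix, columns = (side, lateral, chain) directions.
#' @keywords internal
build_residue_atoms <- function(code3, resindex, resno, chain, ca, frame,
                                with_oxt = FALSE) {
  tpl <- residue_template_offsets(code3, with_oxt = with_oxt)
  xyz <- sweep(tpl$offsets %*% t(frame), 2, ca, "+")
  tibble(
    model = 1L, chain = chain, resindex = as.integer(resindex),
    resno = as.integer(resno), insert = "", resid = code3,
    elety = tpl$name, element = element_from_name(tpl$name),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

#' Isolated free amino acid structure
#'
#' Builds a single free amino acid (backbone with terminal OXT plus side
#' chain) in the package's idealized template geometry. This is the
#' "completely hydrated individual amino acid" whose surface area is the
#' denominator of relative solvent accessibility.
#'
#' @param code One-letter or three-letter amino-acid code.
#' @return Single-residue atom tibble.
#' @export
free_residue <- function(code) {
  code3 <- if (nchar(code) == 1) unname(AA_ONE_TO_THREE[toupper(code)])
           else toupper(code)
  if (is.na(code3) || !code3 %in% names(AA_SIDE_ATOMS)) {
    abort(paste0("unknown amino acid: ", code),
          class = "tailsolv_unsupported_residue_error")
  }
  build_residue_atoms(code3, 1L, 1L, "A", c(0, 0, 0), diag(3),
                      with_oxt = TRUE)
}

# Orthonormal frame with given chain direction (3rd column) and a side
# direction (1st column) as close as possible to `side_hint`.
#' @keywords internal
make_frame <- function(chain_dir, side_hint) {
  ez <- chain_dir / sqrt(sum(chain_dir^2))
  ex <- side_hint - sum(side_hint * ez) * ez
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-8) {  # hint parallel to chain: pick any perpendicular
    ex <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ex <- ex - sum(ex * ez) * ez
    nx <- sqrt(sum(ex^2))
  }
  ex <- ex / nx
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  cbind(ex, ey, ez, deparse.level = 0)
}
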