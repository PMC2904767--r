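# Amino-acid vocabulary shared across the package: three- and one-letter
# codes, heavy-atom topology (backbone + side-chain atom names in PDB
# conventions), atomic masses, and background composition of globular
# proteins.

#' Three-letter to one-letter amino-acid code map
#' @keywords internal
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @keywords internal
AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))

# Side-chain heavy-atom names per residue (backbone N, CA, C, O implied).
#' @keywords internal
AA_SIDE_ATOMS <- list(
  GLY = character(0),
  ALA = "CB",
  SER = c("CB", "OG"),
  CYS = c("CB", "SG"),
  THR = c("CB", "OG1", "CG2"),
  VAL = c("CB", "CG1", "CG2"),
  PRO = c("CB", "CG", "CD"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "SD", "CE"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CB", "CG", "CD1", "NE1", "CE2", "CD2", "CE3", "CZ2", "CZ3", "CH2")
)

#' @keywords internal
ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)

# Background amino-acid frequencies of globular proteins (Swiss-Prot-like
# composition, renormalised to sum to one). Used as the default core
# composition of the synthetic generator.
#' @keywords internal
AA_BACKGROUND_FREQ <- local({
  f <- c(
    A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
    Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
    L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
    S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686
  )
  f / sum(f)
})

# Infer the element of a heavy atom from its PDB atom name.
#' @keywords internal
element_from_name <- function(name) {
  first <- substr(gsub("^[0-9]+", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, NA_character_)
}
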