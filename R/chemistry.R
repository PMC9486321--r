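# Residue and atom chemistry tables shared across the package.

# three-letter amino acid codes and one-letter equivalents
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# modified residues mapped to their parent for typing (kept as protein atoms)
AA_ALIASES <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO", SEP = "SER",
                TPO = "THR", PTR = "TYR")

WATER_NAMES <- c("HOH", "WAT", "DOD")

# DA/DC/DG/DT/DU plus legacy one-letter nucleotide names
DNA_NAMES <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")

PURINES <- c("DA", "DG", "A", "G")

is_amino <- function(residue_name) {
  residue_name %in% names(AA3) | residue_name %in% names(AA_ALIASES)
}

is_nucleotide <- function(residue_name) residue_name %in% DNA_NAMES

is_water_res <- function(residue_name) residue_name %in% WATER_NAMES

canonical_residue <- function(residue_name) {
  hit <- AA_ALIASES[residue_name]
  ifelse(is.na(hit), residue_name, hit)
}

#' One-letter codes for three-letter residue names
#'
#' Modified residues are mapped to their parent type first (e.g. MSE to
#' MET); unknown names give `NA`. Handy for building the alignment query
#' sequence of a structure's chain.
#'
#' @param residue_name character vector of three-letter codes.
#' @return character vector of one-letter codes.
#' @export
aa_one_letter <- function(residue_name) {
  unname(AA3[canonical_residue(residue_name)])
}

# sp2 (carbonyl/carboxyl/aromatic/guanidinium) carbons by residue context;
# everything else carbon is treated as aliphatic.
SP2_CARBON <- list(
  backbone = "C",
  ARG = "CZ", ASP = c("CG"), GLU = c("CD"), ASN = c("CG"), GLN = c("CD"),
  HIS = c("CG", "CD2", "CE1"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  base = c("C2", "C4", "C5", "C6", "C8")
)

# DNA moiety assignment by atom label; sugar = remaining primed atoms
PHOSPHATE_ATOMS <- c("P", "OP1", "OP2", "O1P", "O2P", "OP3", "O5'", "O3'")

dna_moiety <- function(atom_name) {
  out <- rep("base", length(atom_name))
  out[atom_name %in% PHOSPHATE_ATOMS] <- "phosphate"
  out[grepl("'", atom_name, fixed = TRUE) &
        !(atom_name %in% PHOSPHATE_ATOMS)] <- "sugar"
  out
}

# backbone heavy atoms of a protein residue
PROTEIN_BACKBONE <- c("N", "CA", "C", "O", "OXT")
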