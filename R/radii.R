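# Van der Waals radii in the Chothia-style convention used by classic
# accessibility programs: oxygens 1.40, nitrogens 1.65, sp2 carbons 1.76,
# sp3 carbons 1.87, sulfur 1.85, phosphorus 1.90 (angstrom).

CHOTHIA_RADII <- c(N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                   C_SP2 = 1.76, C_SP3 = 1.87)

# element fallback for atoms whose name/context is not recognised
ELEMENT_FALLBACK_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                            H = 1.00, D = 1.00, SE = 1.90, F = 1.47,
                            CL = 1.75, BR = 1.85, I = 1.98)
DEFAULT_FALLBACK_RADIUS <- 1.80

#' Assign van der Waals radii to all atoms of a structure
#'
#' Fills the `vdw_radius` column using a Chothia-style radii set
#' (the convention of classic accessibility programs): O 1.40, N 1.65,
#' S 1.85, P 1.90, sp2 carbon 1.76, sp3 carbon 1.87 angstrom. Carbon
#' hybridisation is resolved from the residue/atom-name context (backbone
#' carbonyl, aromatic rings, carboxylates, nucleobase carbons are sp2).
#' Atoms whose element has no entry fall back to a generic element radius
#' with a warning.
#'
#' @param structure an atom tibble as returned by [read_structure()].
#' @param radii_set name of the radii set; only `"chothia"` is bundled.
#' @return the structure with `vdw_radius` filled for every atom.
#' @export
assign_radii <- function(structure, radii_set = "chothia") {
  if (!identical(radii_set, "chothia")) {
    stop("unknown radii set: ", radii_set, " (bundled: 'chothia')")
  }
  el <- toupper(structure$element)
  res <- canonical_residue(structure$residue_name)
  atom <- structure$atom_name

  r <- rep(NA_real_, nrow(structure))
  r[el == "N"] <- CHOTHIA_RADII[["N"]]
  r[el == "O"] <- CHOTHIA_RADII[["O"]]
  r[el == "S"] <- CHOTHIA_RADII[["S"]]
  r[el == "P"] <- CHOTHIA_RADII[["P"]]

  is_c <- el == "C"
  sp2 <- is_c & (
    (structure$component == "protein" & atom %in% SP2_CARBON$backbone) |
    (structure$component == "dna" & atom %in% SP2_CARBON$base &
       !grepl("'", atom, fixed = TRUE)) |
    purrr::map2_lgl(res, atom, function(rn, an) {
      side <- SP2_CARBON[[rn]]
      !is.null(side) && an %in% side
    })
  )
  r[is_c] <- ifelse(sp2[is_c], CHOTHIA_RADII[["C_SP2"]], CHOTHIA_RADII[["C_SP3"]])
  r[el %in% c("H", "D")] <- ELEMENT_FALLBACK_RADII[["H"]]

  missing <- is.na(r)
  if (any(missing)) {
    fb <- ELEMENT_FALLBACK_RADII[el[missing]]
    fb[is.na(fb)] <- DEFAULT_FALLBACK_RADIUS
    r[missing] <- fb
    heavy_missing <- missing & !structure$is_hydrogen
    if (any(heavy_missing)) {
      warning(sum(heavy_missing),
              " atom(s) with unrecognised element assigned an",
              " element-fallback radius (e.g. ",
              structure$atom_name[which(heavy_missing)[1]], ")")
    }
  }
  structure$vdw_radius <- r
  structure
}
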