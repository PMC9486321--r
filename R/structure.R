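# PDB structure input: parsing (via bio3d), component tagging, altloc
# filtering, chain/residue indexing and a PDB writer for round-tripping.

STRUCTURE_COLS <- c("serial", "atom_name", "altloc", "residue_name", "chain",
                    "residue_number", "insert", "x", "y", "z", "occupancy",
                    "element", "is_hydrogen", "component", "polarity",
                    "moiety", "vdw_radius")

ATOM_KEY <- c("chain", "residue_number", "insert", "residue_name", "atom_name")
RESIDUE_KEY <- c("chain", "residue_number", "insert")

new_structure <- function(atoms, title = "") {
  out <- as_tibble(atoms)
  attr(out, "title") <- title
  class(out) <- c("pdi_structure", class(out))
  out
}

element_from_name <- function(atom_name) {
  nm <- toupper(gsub("['\"*0-9]", "", atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("SE", "FE", "MG", "ZN", "MN", "CL", "BR", "NA", "CA") &
           nchar(nm) == 2 & !grepl("^C[A-Z]$", two),
         two, substr(nm, 1, 1))
}

#' Parse a protein-DNA complex from PDB-format text
#'
#' Reads `ATOM`/`HETATM` records (first `MODEL` only), keeps the
#' highest-occupancy alternate location of each atom, tags every atom with
#' its component (`protein`, `dna`, `water`, `other`) and polarity
#' (`nonpolar` for C/S, `polar` otherwise), and returns one tidy atom
#' tibble. Hydrogens are retained but flagged, so downstream area and
#' counting operations can exclude them.
#'
#' @param text PDB-format text: a single string or a character vector of lines.
#' @return a `pdi_structure` tibble, one row per atom.
#' @seealso [read_structure()] to read from a file, [split_components()],
#'   [assign_radii()].
#' @export
parse_structure <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text

  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]

  rec <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(rec)) stop("no ATOM/HETATM records found: empty structure")
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (nchar(ln) < 54 || anyNA(coords)) {
      stop("unreadable ATOM/HETATM record at line ", i)
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- as_tibble(pdb$atom)

  title <- paste(trimws(substr(lines[startsWith(lines, "TITLE")], 11, 80)),
                 collapse = " ")

  el <- toupper(trimws(a$elesy))
  el[is.na(el) | el == ""] <- element_from_name(a$elety[is.na(el) | el == ""])
  resname <- trimws(a$resid)

  atoms <- tibble(
    serial = a$eleno,
    atom_name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", a$alt),
    residue_name = resname,
    chain = ifelse(is.na(a$chain), "", a$chain),
    residue_number = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = el,
    is_hydrogen = el %in% c("H", "D"),
    component = dplyr::case_when(
      is_water_res(resname) ~ "water",
      is_amino(resname) ~ "protein",
      is_nucleotide(resname) ~ "dna",
      TRUE ~ "other"
    ),
    polarity = ifelse(el %in% c("C", "S"), "nonpolar", "polar"),
    moiety = NA_character_,
    vdw_radius = NA_real_
  )
  atoms$moiety[atoms$component == "dna"] <-
    dna_moiety(atoms$atom_name[atoms$component == "dna"])

  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in structure")
  }

  # altloc: keep the highest-occupancy conformer, ties by altloc letter order
  atoms <- atoms |>
    group_by(across(all_of(ATOM_KEY))) |>
    arrange(dplyr::desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$serial)

  new_structure(atoms, title = title)
}

#' Read a structure from a PDB file
#'
#' @param file path to a PDB-format file.
#' @inherit parse_structure return
#' @export
read_structure <- function(file) {
  parse_structure(readLines(file, warn = FALSE))
}

#' Split a complex into protein, DNA and water components
#'
#' @param structure a parsed `pdi_structure`.
#' @param protein_chains,dna_chains character vectors of chain identifiers.
#'   The two sets must not overlap. Waters are collected from the whole
#'   structure regardless of chain; atoms in unselected chains are dropped.
#' @return a list with elements `protein`, `dna` and `waters`, each a
#'   `pdi_structure`.
#' @export
split_components <- function(structure, protein_chains, dna_chains) {
  if (length(intersect(protein_chains, dna_chains)) > 0) {
    stop("protein and DNA chain selections overlap: ",
         paste(intersect(protein_chains, dna_chains), collapse = ", "))
  }
  available <- unique(structure$chain[structure$component != "water"])
  unknown <- setdiff(c(protein_chains, dna_chains), available)
  if (length(unknown) > 0) {
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "),
         " (available: ", paste(available, collapse = ", "), ")")
  }
  for (ch in protein_chains) {
    in_ch <- structure$chain == ch & structure$component != "water"
    if (!any(structure$component[in_ch] == "protein")) {
      stop("chain ", ch, " requested as protein but contains no amino acids")
    }
  }
  for (ch in dna_chains) {
    in_ch <- structure$chain == ch & structure$component != "water"
    if (!any(structure$component[in_ch] == "dna")) {
      stop("chain ", ch, " requested as DNA but contains no nucleotides")
    }
  }
  ttl <- attr(structure, "title")
  list(
    protein = new_structure(
      filter(structure, .data$chain %in% protein_chains,
             .data$component == "protein"), ttl),
    dna = new_structure(
      filter(structure, .data$chain %in% dna_chains,
             .data$component == "dna"), ttl),
    waters = new_structure(filter(structure, .data$component == "water"), ttl)
  )
}

#' List the residues of a structure
#'
#' @param structure a `pdi_structure`.
#' @return a tibble with one row per residue (chain, number, insertion code,
#'   name, component), in atom order.
#' @export
structure_residues <- function(structure) {
  structure |>
    distinct(.data$chain, .data$residue_number, .data$insert,
             .data$residue_name, .data$component)
}

#' Write a structure as PDB-format text
#'
#' @param structure a `pdi_structure`.
#' @param file optional path; when `NULL` the text is returned only.
#' @return the PDB text lines, invisibly when `file` is given.
#' @export
write_pdb <- function(structure, file = NULL) {
  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4, substr(name, 1, 4),
           ifelse(nchar(element) == 2, sprintf("%-4s", name),
                  sprintf(" %-3s", name)))
  }
  rec <- ifelse(structure$component %in% c("protein", "dna"), "ATOM  ", "HETATM")
  lines <- sprintf(
    "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, structure$serial %% 100000L,
    fmt_name(structure$atom_name, structure$element),
    substr(paste0(structure$altloc, " "), 1, 1),
    structure$residue_name,
    substr(paste0(structure$chain, " "), 1, 1),
    structure$residue_number,
    substr(paste0(structure$insert, " "), 1, 1),
    structure$x, structure$y, structure$z,
    structure$occupancy, 0,
    structure$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
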