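# The three discriminative interface features: residue propensity score
# (Rp), potential hydrogen-bond donor count (Dp) and - via the conservation
# module - the conserved residue count (Ncons); plus interface secondary
# structure classification.

# side-chain atoms counted as potential hydrogen-bond donors
DONOR_ATOMS <- tibble::tribble(
  ~residue_name, ~atom_name,
  "ARG", "NE", "ARG", "NH1", "ARG", "NH2",
  "HIS", "ND1", "HIS", "NE2",
  "LYS", "NZ",
  "ASN", "ND2",
  "GLN", "NE2",
  "TRP", "NE1",
  "SER", "OG",
  "THR", "OG1",
  "TYR", "OH"
)

#' Synthetic residue propensity table
#'
#' A bundled, synthetic log-scale propensity table (positive = enriched at
#' protein-DNA interfaces relative to the protein surface). The values
#' encode the familiar enrichment trends (arginine/lysine and the
#' hydroxyl/amide residues enriched, acidic and large hydrophobic residues
#' depleted) but are synthetic: they were not fitted to any structure set.
#' Derive a real table from your own training complexes with
#' [compute_propensity_table()].
#'
#' @return a tibble with `residue_name` (three-letter code) and `p`.
#' @export
propensity_table_synthetic <- function() {
  tibble::tribble(
    ~residue_name, ~p,
    "ALA", -0.10, "ARG",  0.93, "ASN",  0.34, "ASP", -0.50, "CYS", -0.30,
    "GLN",  0.21, "GLU", -0.63, "GLY",  0.14, "HIS",  0.40, "ILE", -0.33,
    "LEU", -0.35, "LYS",  0.57, "MET", -0.15, "PHE", -0.18, "PRO", -0.12,
    "SER",  0.16, "THR",  0.21, "TRP",  0.10, "TYR",  0.26, "VAL", -0.29
  )
}

#' Derive a residue propensity table from training complexes
#'
#' For each amino-acid type, `p_i = ln(f_int,i / f_surf,i)`: the log ratio
#' of its frequency among interface residues to its frequency among surface
#' residues, pooled over the training complexes, with one pseudo-count per
#' type.
#'
#' @param complexes a list; each element has `protein` and `dna`
#'   `pdi_structure` components with radii assigned.
#' @param ... passed to [find_interface()].
#' @return a tibble with `residue_name` and `p`.
#' @export
compute_propensity_table <- function(complexes, ...) {
  aa <- names(AA3)
  n_int <- setNames(rep(1, 20), aa)   # pseudo-counts
  n_surf <- setNames(rep(1, 20), aa)
  for (cx in complexes) {
    im <- find_interface(cx$protein, cx$dna, ...)
    asa_res <- im$asa$protein_free |>
      group_by(across(all_of(RESIDUE_KEY)), .data$residue_name) |>
      summarise(area = sum(.data$area), .groups = "drop") |>
      filter(.data$area > 1)  # solvent-exposed residues
    int_res <- filter(im$residues, .data$component == "protein")
    surf_res <- anti_join(asa_res, int_res, by = RESIDUE_KEY)
    ti <- table(canonical_residue(int_res$residue_name))
    ts <- table(canonical_residue(surf_res$residue_name))
    n_int[names(ti)[names(ti) %in% aa]] <-
      n_int[names(ti)[names(ti) %in% aa]] + ti[names(ti) %in% aa]
    n_surf[names(ts)[names(ts) %in% aa]] <-
      n_surf[names(ts)[names(ts) %in% aa]] + ts[names(ts) %in% aa]
  }
  f_int <- n_int / sum(n_int)
  f_surf <- n_surf / sum(n_surf)
  tibble(residue_name = aa, p = log(f_int / f_surf))
}

#' Interface amino-acid composition
#'
#' @param im a `pdi_interface`.
#' @param component which component to tally (default protein).
#' @return a tibble with `residue_name` and count `n` (`sum(n)` equals the
#'   component's interface residue count).
#' @export
interface_composition <- function(im, component = "protein") {
  im$residues |>
    filter(.data$component == .env$component) |>
    mutate(residue_name = canonical_residue(.data$residue_name)) |>
    dplyr::count(.data$residue_name)
}

#' Residue propensity score Rp
#'
#' `Rp = sum_i n_i * p_i` over amino-acid types, where `n_i` is the number
#' of interface residues of type `i` and `p_i` its interface propensity.
#'
#' @param composition a tibble with `residue_name` and `n`
#'   (see [interface_composition()]), or a named count vector.
#' @param table a propensity table (`residue_name`, `p`); defaults to the
#'   bundled synthetic table.
#' @return the score (a single number).
#' @export
residue_propensity_score <- function(composition,
                                     table = propensity_table_synthetic()) {
  if (!is.data.frame(composition)) {
    composition <- tibble(residue_name = names(composition),
                          n = as.integer(composition))
  }
  if (nrow(composition) == 0) return(0)
  joined <- left_join(composition, table, by = "residue_name")
  if (anyNA(joined$p)) {
    stop("no propensity for residue type(s): ",
         paste(joined$residue_name[is.na(joined$p)], collapse = ", "))
  }
  sum(joined$n * joined$p)
}

#' Count potential hydrogen-bond donors (Dp)
#'
#' Counts the designated side-chain donor atoms (Arg NE/NH1/NH2, His
#' ND1/NE2, Lys NZ, Asn ND2, Gln NE2, Trp NE1, Ser OG, Thr OG1, Tyr OH)
#' with accessible surface area of at least `min_asa` (default 10 angstrom
#' squared) among the residues of the scored region. The default context is
#' the ASA of the isolated protein, restricted to its interface residues.
#'
#' @param protein the protein component.
#' @param asa an ASA map for the relevant context; defaults to the isolated
#'   protein's ASA.
#' @param residues optional residue tibble (rows with `chain`,
#'   `residue_number`, `insert`) restricting the scored region, e.g.
#'   `im$residues`; `NULL` scores the whole protein.
#' @param min_asa accessibility threshold (angstrom squared).
#' @param probe_radius,n_sphere_points used only when `asa` is computed here.
#' @return a list with `dp` (the count) and `donors` (one row per counted
#'   atom with its area).
#' @export
count_potential_donors <- function(protein, asa = NULL, residues = NULL,
                                   min_asa = 10, probe_radius = 1.4,
                                   n_sphere_points = 960) {
  if (is.null(asa)) asa <- compute_asa(protein, probe_radius, n_sphere_points)
  donors <- asa |>
    mutate(residue_name = canonical_residue(.data$residue_name)) |>
    semi_join(DONOR_ATOMS, by = c("residue_name", "atom_name"))
  if (!is.null(residues)) {
    donors <- semi_join(donors, residues, by = RESIDUE_KEY)
  }
  donors <- filter(donors, .data$area >= min_asa)
  list(dp = nrow(donors), donors = donors)
}

backbone_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb, sum(n1 * n2)) * 180 / pi
}

#' Backbone dihedral angles of a protein chain
#'
#' @param protein the protein component.
#' @return a tibble with one row per residue: `phi`, `psi` (degrees; `NA`
#'   at chain termini or with missing backbone atoms).
#' @export
backbone_dihedrals <- function(protein) {
  bb <- protein |>
    filter(.data$atom_name %in% c("N", "CA", "C"), !.data$is_hydrogen) |>
    arrange(.data$chain, .data$residue_number, .data$insert)
  res <- bb |>
    distinct(.data$chain, .data$residue_number, .data$insert,
             .data$residue_name)
  get_atom <- function(ch, rn, ins, an) {
    hit <- bb[bb$chain == ch & bb$residue_number == rn & bb$insert == ins &
                bb$atom_name == an, ]
    if (nrow(hit) == 0) return(NULL)
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  res$phi <- NA_real_
  res$psi <- NA_real_
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rn <- res$residue_number[i]; ins <- res$insert[i]
    N <- get_atom(ch, rn, ins, "N"); CA <- get_atom(ch, rn, ins, "CA")
    C <- get_atom(ch, rn, ins, "C")
    Cprev <- get_atom(ch, rn - 1, ins, "C")
    Nnext <- get_atom(ch, rn + 1, ins, "N")
    if (!is.null(Cprev) && !is.null(N) && !is.null(CA) && !is.null(C)) {
      res$phi[i] <- backbone_dihedral(Cprev, N, CA, C)
    }
    if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nnext)) {
      res$psi[i] <- backbone_dihedral(N, CA, C, Nnext)
    }
  }
  res
}

#' Classify interface secondary structure
#'
#' Per-residue helix/strand assignment by backbone dihedral windows
#' (helix: phi in \[-100, -30\], psi in \[-80, -5\]; strand: phi in
#' \[-180, -40\], psi in \[90, 180\] or \[-180, -170\]); residues with
#' missing backbone are `other`. The interface class follows from the
#' interface-residue fractions `f_H`, `f_E`: `alpha` if `f_H >= 0.35` and
#' `f_E < 0.10`; `beta` if `f_E >= 0.35` and `f_H < 0.10`; `alphabeta` if
#' both are at least 0.10; otherwise `NR` (non-regular).
#'
#' @param protein the protein component.
#' @param im a `pdi_interface`.
#' @return a list with `class` (one of `"alpha"`, `"beta"`, `"alphabeta"`,
#'   `"NR"`), the fractions `f_helix`, `f_strand`, and the per-residue
#'   assignment tibble.
#' @export
classify_secondary_structure <- function(protein, im) {
  dih <- backbone_dihedrals(protein)
  dih$ss <- "other"
  helix <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= -100 & dih$phi <= -30 & dih$psi >= -80 & dih$psi <= -5
  strand <- !is.na(dih$phi) & !is.na(dih$psi) &
    dih$phi >= -180 & dih$phi <= -40 &
    ((dih$psi >= 90 & dih$psi <= 180) | (dih$psi >= -180 & dih$psi <= -170))
  dih$ss[strand] <- "strand"
  dih$ss[helix] <- "helix"

  ires <- im$residues |>
    filter(.data$component == "protein") |>
    select(all_of(RESIDUE_KEY))
  idih <- semi_join(dih, ires, by = RESIDUE_KEY)
  f_h <- if (nrow(idih) > 0) mean(idih$ss == "helix") else 0
  f_e <- if (nrow(idih) > 0) mean(idih$ss == "strand") else 0
  cls <- if (f_h >= 0.35 && f_e < 0.10) "alpha"
  else if (f_e >= 0.35 && f_h < 0.10) "beta"
  else if (f_h >= 0.10 && f_e >= 0.10) "alphabeta"
  else "NR"
  list(class = cls, f_helix = f_h, f_strand = f_e, residues = dih)
}

#' Feature vector of a candidate interface
#'
#' Assembles the three discriminative features of an interface: the residue
#' propensity score `Rp` of its protein interface composition, the
#' potential-donor count `Dp` among its protein interface residues
#' (isolated-protein ASA context), and - when an alignment is supplied -
#' the conserved-residue count `Ncons` of the analysed chain.
#'
#' @param protein,im the protein component and its `pdi_interface`.
#' @param aln optional `pdi_alignment` for `Ncons` (otherwise `NA`).
#' @param chain chain scored for conservation; default first protein chain.
#' @param propensity propensity table for `Rp`.
#' @param donor_min_asa ASA threshold for `Dp` (angstrom squared).
#' @return a one-row tibble: `rp`, `dp`, `ncons`, `n_interface_residues`.
#' @export
interface_features <- function(protein, im, aln = NULL, chain = NULL,
                               propensity = propensity_table_synthetic(),
                               donor_min_asa = 10) {
  rp <- residue_propensity_score(interface_composition(im), propensity)
  dp <- count_potential_donors(
    protein, asa = im$asa$protein_free,
    residues = filter(im$residues, .data$component == "protein"),
    min_asa = donor_min_asa)$dp
  ncons <- NA_integer_
  if (!is.null(aln)) {
    prof <- interface_entropy_profile(aln, im, protein, chain = chain)
    ncons <- attr(prof, "n_cons")
  }
  tibble(rp = rp, dp = dp, ncons = ncons,
         n_interface_residues = sum(im$residues$component == "protein"))
}
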