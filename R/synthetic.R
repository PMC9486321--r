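# Deterministic generators of toy protein-DNA complexes, synthetic
# alignments and docking-decoy sets. Geometry is idealised: a standard
# alpha-helical peptide (internal-coordinate build) facing an idealised
# B-DNA duplex (fibre-like cylindrical template, rise 3.38 A, twist 36 deg).
# Sufficient for geometric and counting tests; no physical realism beyond
# geometry is attempted.

# run code under a seed without disturbing the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  invisible(function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

# place atom D given A, B, C: |CD| = bond, angle(B,C,D), torsion(A,B,C,D)
place_atom <- function(pa, pb, pc, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- pc - pb; bc <- bc / sqrt(sum(bc^2))
  ab <- pb - pa; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          -bond * sin(tor) * sin(ang))
  as.vector(pc + cbind(bc, m, n) %*% d2)
}

peptide_atom_row <- function(name, res_i, resname, xyz, chain = "A") {
  el <- substr(gsub("[0-9]", "", name), 1, 1)
  tibble(serial = NA_integer_, atom_name = name, altloc = "",
         residue_name = resname, chain = chain, residue_number = res_i,
         insert = "", x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
         element = el, is_hydrogen = FALSE, component = "protein",
         polarity = ifelse(el %in% c("C", "S"), "nonpolar", "polar"),
         moiety = NA_character_, vdw_radius = NA_real_)
}

#' Build an idealised peptide with standard backbone geometry
#'
#' Residues are placed by internal coordinates (standard bond lengths and
#' angles, omega = 180 deg) at the supplied phi/psi, default an ideal
#' alpha helix (-57/-47). Backbone N, CA, C, O plus CB are built for all
#' residues except glycine; serine and threonine additionally get their
#' hydroxyl oxygen (OG/OG1) so donor and hydrogen-bond fixtures have real
#' atoms. Other side chains are truncated at CB.
#'
#' @param sequence character vector of three-letter residue codes.
#' @param phi,psi backbone dihedrals in degrees (scalar or per-residue).
#' @param chain chain identifier.
#' @return a `pdi_structure` (radii not yet assigned).
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chain = "A") {
  n <- length(sequence)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  rows <- vector("list", 0)
  # residue 1 backbone seed
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C <- CA + 1.525 * c(cos(pi - ang), sin(pi - ang), 0)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in seq_len(n)) {
    res <- sequence[i]
    if (i > 1) {
      N <- place_atom(prevN, prevCA, prevC, 1.329, 116.2, psi[i - 1])
      CA <- place_atom(prevCA, prevC, N, 1.458, 121.7, 180)
      C <- place_atom(prevC, N, CA, 1.525, 111.2, phi[i])
    }
    O <- place_atom(N, CA, C, 1.231, 120.8, psi[i] + 180)
    rows <- c(rows, list(
      peptide_atom_row("N", i, res, N, chain),
      peptide_atom_row("CA", i, res, CA, chain),
      peptide_atom_row("C", i, res, C, chain),
      peptide_atom_row("O", i, res, O, chain)))
    if (res != "GLY") {
      CB <- place_atom(N, C, CA, 1.53, 110.1, 122.5)
      rows <- c(rows, list(peptide_atom_row("CB", i, res, CB, chain)))
      if (res %in% c("SER", "THR")) {
        og <- place_atom(N, CA, CB, 1.42, 110.8, -65)
        rows <- c(rows, list(peptide_atom_row(
          ifelse(res == "SER", "OG", "OG1"), i, res, og, chain)))
      }
    }
    prevN <- N; prevCA <- CA; prevC <- C
  }
  out <- bind_rows(rows)
  out$serial <- seq_len(nrow(out))
  new_structure(out, title = "synthetic peptide")
}

# planar base templates with standard ring bond geometry; local 2D frame
# with the glycosidic nitrogen (N9/N1) at the origin, the ring extending
# along +bx
base_local <- function(resname) {
  if (resname %in% PURINES) {
    x6 <- if (resname %in% c("DA", "A")) "N6" else "O6"
    tibble::tribble(
      ~atom_name, ~bx, ~by,
      "N9", 0.00, 0.00, "C8", 0.70, 1.17, "N7", 2.04, 0.98,
      "C5", 2.17, -0.40, "C6", 3.24, -1.25, x6, 4.46, -0.90,
      "N1", 2.98, -2.57, "C2", 1.74, -3.02, "N3", 0.67, -2.28,
      "C4", 0.89, -0.94
    )
  } else {
    x4 <- if (resname %in% c("DC", "C")) "N4" else "O4"
    tibble::tribble(
      ~atom_name, ~bx, ~by,
      "N1", 0.00, 0.00, "C2", 1.24, -0.70, "O2", 1.20, -1.93,
      "N3", 2.41, -0.02, "C4", 2.40, 1.33, x4, 3.54, 2.01,
      "C5", 1.14, 2.04, "C6", 0.00, 1.38
    )
  }
}

# per-nucleotide atom template: axial offset (A), radius (A), phase (deg);
# sugar/phosphate placed on the cylinder, the base as a planar ring lying in
# the cross-sectional plane, attached inward of C1' by the glycosidic bond
nt_template <- function(resname) {
  sugar_phos <- tibble::tribble(
    ~atom_name, ~a, ~r, ~phi,
    "P", 2.0, 8.9, 0, "OP1", 2.3, 10.1, 5, "OP2", 3.2, 9.0, -8,
    "O5'", 1.0, 8.0, -5, "C5'", 0.6, 7.4, -12, "C4'", 0.0, 7.0, 0,
    "O4'", -0.8, 6.4, -8, "C3'", -0.3, 7.6, 12, "O3'", 0.3, 8.7, 25,
    "C2'", -1.2, 6.7, 15, "C1'", -1.3, 5.9, 0
  )
  bl <- base_local(resname)
  # rotate the ring in-plane so it extends tangentially rather than through
  # the axis (the two strands are not base-paired in this idealisation)
  delta <- (if (resname %in% PURINES) -40 else 40) * pi / 180
  bx <- bl$bx * cos(delta) - bl$by * sin(delta)
  by <- bl$bx * sin(delta) + bl$by * cos(delta)
  # glycosidic attachment: 1.47 A radially inward of C1'
  u <- (5.9 - 1.47) - bx      # radial coordinate
  w <- by                     # tangential coordinate
  base <- tibble(atom_name = bl$atom_name, a = -1.3,
                 r = sqrt(u^2 + w^2), phi = atan2(w, u) * 180 / pi)
  bind_rows(sugar_phos, base)
}

DNA_COMPLEMENT <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")

#' Build an idealised B-DNA duplex fragment
#'
#' Fibre-like geometry: rise 3.38 angstrom, twist 36 degrees per base pair,
#' duplex axis along x. Atom positions come from a cylindrical per-atom
#' template (phosphate, sugar and base moieties all present); the second
#' strand is the antiparallel complementary copy.
#'
#' @param sequence character vector of first-strand nucleotides
#'   (`DA`/`DC`/`DG`/`DT`).
#' @param chain1,chain2 chain identifiers of the two strands.
#' @param rise,twist helical parameters (angstrom, degrees).
#' @param strand2_phase angular offset of the second strand (degrees).
#' @return a `pdi_structure` (radii not yet assigned).
#' @export
build_bdna <- function(sequence, chain1 = "B", chain2 = "C",
                       rise = 3.38, twist = 36, strand2_phase = 180) {
  stopifnot(all(sequence %in% names(DNA_COMPLEMENT)))
  n <- length(sequence)
  rows <- vector("list", 0)
  add_nt <- function(resname, k, chain, res_i, flip) {
    tpl <- nt_template(resname)
    theta <- (k * twist) * pi / 180
    if (flip) {
      ax <- k * rise - tpl$a
      ang <- theta + (strand2_phase - tpl$phi) * pi / 180
    } else {
      ax <- k * rise + tpl$a
      ang <- theta + tpl$phi * pi / 180
    }
    el <- substr(tpl$atom_name, 1, 1)
    tibble(serial = NA_integer_, atom_name = tpl$atom_name, altloc = "",
           residue_name = resname, chain = chain, residue_number = res_i,
           insert = "", x = ax, y = tpl$r * cos(ang), z = tpl$r * sin(ang),
           occupancy = 1, element = el, is_hydrogen = FALSE,
           component = "dna",
           polarity = ifelse(el %in% c("C", "S"), "nonpolar", "polar"),
           moiety = dna_moiety(tpl$atom_name), vdw_radius = NA_real_)
  }
  for (k in seq_len(n) - 1L) {
    rows <- c(rows, list(add_nt(sequence[k + 1], k, chain1, k + 1L, FALSE)))
  }
  comp <- unname(DNA_COMPLEMENT[sequence])
  for (k in seq_len(n) - 1L) {
    rows <- c(rows, list(add_nt(comp[k + 1], k, chain2, n - k, TRUE)))
  }
  out <- bind_rows(rows)
  out$serial <- seq_len(nrow(out))
  new_structure(out, title = "synthetic B-DNA fragment")
}

# rigid transform mapping the peptide onto a canonical frame: CA centroid at
# the origin, principal CA axis along +x (first to last CA)
canonical_peptide_frame <- function(peptide) {
  ca <- filter(peptide, .data$atom_name == "CA")
  xyz <- cbind(ca$x, ca$y, ca$z)
  ctr <- colMeans(xyz)
  ev <- eigen(cov(sweep(xyz, 2, ctr)), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * ax) < 0) ax <- -ax
  # complete a right-handed frame deterministically
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e2 <- ref - sum(ref * ax) * ax
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(ax[2] * e2[3] - ax[3] * e2[2], ax[3] * e2[1] - ax[1] * e2[3],
          ax[1] * e2[2] - ax[2] * e2[1])
  list(center = ctr, rot = rbind(ax, e2, e3))
}

apply_frame <- function(structure, frame) {
  xyz <- sweep(cbind(structure$x, structure$y, structure$z), 2, frame$center)
  new_xyz <- xyz %*% t(frame$rot)
  structure$x <- new_xyz[, 1]; structure$y <- new_xyz[, 2]
  structure$z <- new_xyz[, 3]
  structure
}

water_row <- function(i, xyz, label) {
  tibble(serial = NA_integer_, atom_name = "O", altloc = "",
         residue_name = "HOH", chain = "W", residue_number = i, insert = "",
         x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1, element = "O",
         is_hydrogen = FALSE, component = "water", polarity = "polar",
         moiety = NA_character_, vdw_radius = NA_real_)
}

# place a water equidistant (target_d) from two atoms; tries several
# perpendicular directions and returns the first clash-free position
bisector_water <- function(p1, p2, target_d, others_xyz, min_clear = 2.2) {
  mid <- (p1 + p2) / 2
  v <- p2 - p1
  d <- sqrt(sum(v^2))
  if (d >= 2 * target_d) return(NULL)
  h <- sqrt(target_d^2 - (d / 2)^2)
  v <- v / d
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- ref - sum(ref * v) * v; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(v[2] * u1[3] - v[3] * u1[2], v[3] * u1[1] - v[1] * u1[3],
          v[1] * u1[2] - v[2] * u1[1])
  for (t in seq(0, 330, by = 30) * pi / 180) {
    pos <- mid + h * (cos(t) * u1 + sin(t) * u2)
    dd <- sqrt(colSums((t(others_xyz) - pos)^2))
    if (min(dd) >= min_clear) return(pos)
  }
  NULL
}

#' Generate a toy protein-DNA complex with known ground truth
#'
#' An idealised alpha-helical peptide (chain A) is placed parallel to an
#' idealised B-DNA duplex (chains B and C) at a controlled axis separation,
#' bridging waters are planted equidistant between a protein hydroxyl/amide
#' oxygen-nitrogen and a DNA acceptor oxygen, and far (non-interface)
#' waters are placed on the opposite face. The generator records which
#' waters were planted as bridging so tests can compare pipeline output
#' against construction. Atom pairs closer than 1 angstrom abort with an
#' error; the DNA phase is auto-adjusted to avoid steric clashes.
#'
#' @param sequence three-letter peptide sequence; default a mixed 24-mer.
#' @param n_bp number of base pairs (first-strand sequence is a fixed
#'   GCAT... repeat unless `dna_sequence` is given).
#' @param dna_sequence optional first-strand nucleotide codes.
#' @param axis_separation distance between peptide and DNA axes (angstrom).
#' @param dna_offset axial (x) shift of the DNA centre relative to the
#'   peptide centre (angstrom).
#' @param dna_phase rotation of the DNA about its own axis (degrees).
#' @param n_bridging_waters,n_far_waters planted water counts.
#' @param seed RNG seed (water jitter); same seed, same structure.
#' @return a list: `structure` (full complex, radii assigned), `protein`,
#'   `dna`, `waters` components, and `truth` (planted bridging/far water
#'   residue numbers, DNA centre, chain sets).
#' @export
make_toy_complex <- function(sequence = NULL, n_bp = 8, dna_sequence = NULL,
                             axis_separation = 13.5, dna_offset = 0,
                             dna_phase = 0, n_bridging_waters = 1,
                             n_far_waters = 1, seed = 1) {
  restore <- local_seed(seed)
  on.exit(restore())
  if (is.null(sequence)) {
    sequence <- rep_len(c("SER", "ALA", "LEU", "THR", "GLY", "ASN"), 24)
  }
  if (is.null(dna_sequence)) {
    dna_sequence <- rep_len(c("DG", "DC", "DA", "DT"), n_bp)
  }
  pep <- build_peptide(sequence)
  pep <- apply_frame(pep, canonical_peptide_frame(pep))

  dna_len <- (length(dna_sequence) - 1) * 3.38
  make_dna_at <- function(phase) {
    dna <- build_bdna(dna_sequence)
    theta <- phase * pi / 180
    y0 <- dna$y * cos(theta) - dna$z * sin(theta)
    z0 <- dna$y * sin(theta) + dna$z * cos(theta)
    dna$x <- dna$x - dna_len / 2 + dna_offset
    dna$y <- y0 + axis_separation
    dna$z <- z0
    dna
  }
  # auto-resolve steric clashes by stepping the DNA phase; accept the first
  # phase with comfortable clearance, falling back to the best available
  pep_xyz <- cbind(pep$x, pep$y, pep$z)
  clearance <- function(cand) {
    min(sqrt(pmax(outer(rowSums(pep_xyz^2),
                        rowSums(cbind(cand$x, cand$y, cand$z)^2), "+") -
               2 * pep_xyz %*% t(cbind(cand$x, cand$y, cand$z)), 0)))
  }
  dna <- NULL
  best <- NULL; best_clear <- -Inf
  for (dphi in seq(0, 174, by = 6)) {
    cand <- make_dna_at(dna_phase + dphi)
    cl <- clearance(cand)
    if (cl >= 1.8) { dna <- cand; break }
    if (cl > best_clear) { best <- cand; best_clear <- cl }
  }
  if (is.null(dna)) {
    if (best_clear >= 1.2) dna <- best
    else stop("could not place DNA without steric clashes")
  }

  solute <- bind_rows(pep, dna)
  solute_xyz <- cbind(solute$x, solute$y, solute$z)

  # plant bridging waters between protein polar atoms and DNA oxygens
  wrows <- list()
  truth_bridging <- integer(0)
  wi <- 0L
  if (n_bridging_waters > 0) {
    ppol <- filter(pep, .data$element %in% c("O", "N"),
                   !(.data$atom_name %in% c("N")))
    dacc <- filter(dna, .data$element == "O")
    pxyz <- cbind(ppol$x, ppol$y, ppol$z)
    dxyz <- cbind(dacc$x, dacc$y, dacc$z)
    dd <- sqrt(pmax(outer(rowSums(pxyz^2), rowSums(dxyz^2), "+") -
                      2 * pxyz %*% t(dxyz), 0))
    cand <- which(dd > 3.2 & dd < 5.5, arr.ind = TRUE)
    cand <- cand[order(dd[cand]), , drop = FALSE]
    placed_xyz <- solute_xyz
    for (ci in seq_len(nrow(cand))) {
      if (length(truth_bridging) >= n_bridging_waters) break
      p1 <- pxyz[cand[ci, 1], ]; p2 <- dxyz[cand[ci, 2], ]
      pos <- bisector_water(p1, p2, 2.8, placed_xyz)
      if (is.null(pos)) next
      wi <- wi + 1L
      wrows <- c(wrows, list(water_row(wi, pos, "bridging")))
      truth_bridging <- c(truth_bridging, wi)
      placed_xyz <- rbind(placed_xyz, pos)
    }
    if (length(truth_bridging) < n_bridging_waters) {
      stop("could not plant ", n_bridging_waters, " bridging water(s); ",
           "geometry too sparse")
    }
  }
  truth_far <- integer(0)
  if (n_far_waters > 0) {
    for (k in seq_len(n_far_waters)) {
      wi <- wi + 1L
      pos <- c(stats::runif(1, -5, 5), -12 - 2 * k, stats::runif(1, -2, 2))
      wrows <- c(wrows, list(water_row(wi, pos, "far")))
      truth_far <- c(truth_far, wi)
    }
  }

  all_atoms <- bind_rows(solute, bind_rows(wrows))
  all_atoms$serial <- seq_len(nrow(all_atoms))
  xyz <- cbind(all_atoms$x, all_atoms$y, all_atoms$z)
  dmat <- dist(xyz)
  if (min(dmat) < 1.0) stop("generator produced atoms closer than 1 angstrom")

  structure_full <- assign_radii(new_structure(all_atoms,
                                               title = "synthetic complex"))
  comps <- split_components(structure_full, "A", c("B", "C"))
  list(
    structure = structure_full,
    protein = comps$protein, dna = comps$dna, waters = comps$waters,
    truth = list(bridging_waters = truth_bridging, far_waters = truth_far,
                 dna_center_x = dna_offset, protein_chains = "A",
                 dna_chains = c("B", "C"))
  )
}

#' Generate a synthetic multiple sequence alignment
#'
#' Homologs are derived from the query by independent per-column
#' substitution: column `j` of a homolog is replaced, with probability
#' `rates[j]`, by a uniformly random amino acid. Columns with rate 0 are
#' perfectly conserved (entropy 0); rate 1 approaches alphabet-uniform
#' entropy.
#'
#' @param query one-letter query sequence (string or character vector).
#' @param n_seqs total number of sequences including the query.
#' @param rates per-column substitution rates in \[0, 1\] (recycled).
#' @param seed RNG seed; same seed, same alignment.
#' @return a `pdi_alignment` whose first row is the query.
#' @export
make_synthetic_msa <- function(query, n_seqs = 50, rates = 0.3, seed = 1) {
  restore <- local_seed(seed)
  on.exit(restore())
  q <- if (length(query) == 1) strsplit(query, "")[[1]] else query
  L <- length(q)
  rates <- rep_len(rates, L)
  stopifnot(all(rates >= 0 & rates <= 1))
  aa <- unname(AA3)
  seqs <- character(n_seqs)
  seqs[1] <- paste(q, collapse = "")
  for (s in 2:n_seqs) {
    row <- q
    hit <- stats::runif(L) < rates
    if (any(hit)) row[hit] <- sample(aa, sum(hit), replace = TRUE)
    seqs[s] <- paste(row, collapse = "")
  }
  new_alignment(c("query", paste0("hom_", seq_len(n_seqs - 1))), seqs)
}

move_dna <- function(structure, dna_chains, dx = 0, phase = 0,
                     axis_y = NULL, axis_z = 0) {
  sel <- structure$chain %in% dna_chains & structure$component == "dna"
  if (phase != 0) {
    if (is.null(axis_y)) axis_y <- mean(structure$y[sel])
    th <- phase * pi / 180
    yy <- structure$y[sel] - axis_y
    zz <- structure$z[sel] - axis_z
    structure$y[sel] <- axis_y + yy * cos(th) - zz * sin(th)
    structure$z[sel] <- axis_z + yy * sin(th) + zz * cos(th)
  }
  structure$x[sel] <- structure$x[sel] + dx
  structure
}

#' Generate a docking-decoy set by rigid DNA re-placement
#'
#' Decoys are built from a toy complex by rigidly sliding (and slightly
#' re-phasing) the DNA along the peptide so that it contacts other surface
#' patches. The residue overlap of each decoy interface with the native
#' interface follows the requested schedule: an overlap of 0 places the
#' DNA far enough that no native interface residue is shared (verified
#' against the measured interface on the first decoy of each placement
#' family); fractional overlaps are solved by bisection on the measured
#' overlap.
#'
#' @param complex a toy complex from [make_toy_complex()].
#' @param n_decoys number of decoys.
#' @param overlap target overlap fraction(s), recycled over decoys.
#' @param seed RNG seed for placement jitter.
#' @param tol acceptable deviation for fractional-overlap targets.
#' @param n_sphere_points quadrature points used when measuring overlaps.
#' @return a list of decoy structures (full complexes); each carries the
#'   applied shift as attribute `dna_shift`.
#' @export
make_decoy_set <- function(complex, n_decoys = 100, overlap = 0, seed = 1,
                           tol = 0.1, n_sphere_points = 960) {
  restore <- local_seed(seed)
  on.exit(restore())
  st <- complex$structure
  truth <- complex$truth
  targets <- rep_len(overlap, n_decoys)

  im_native <- find_interface(complex$protein, complex$dna,
                              n_sphere_points = n_sphere_points)
  nat_res <- filter(im_native$residues, .data$component == "protein")
  if (nrow(nat_res) == 0) stop("native complex has an empty interface")

  pep_ca <- filter(complex$protein, .data$atom_name == "CA")
  x_pep <- range(pep_ca$x)
  nat_x <- range(filter(pep_ca, .data$residue_number %in%
                          nat_res$residue_number)$x)
  dna_x <- range(complex$dna$x)
  dna_half <- diff(dna_x) / 2
  dna_cx <- mean(dna_x)
  # safety margin beyond the native residues' CA range: max atom offset from
  # CA (~3.5 A) plus the occlusion distance of two expanded spheres (~6.6 A)
  reach <- 10.5

  measure_overlap <- function(decoy_st) {
    comps <- split_components(decoy_st, truth$protein_chains,
                              truth$dna_chains)
    suppressWarnings(
      im_d <- find_interface(comps$protein, comps$dna,
                             n_sphere_points = n_sphere_points,
                             asa_protein_free = im_native$asa$protein_free,
                             asa_dna_free = im_native$asa$dna_free))
    interface_overlap(im_native, im_d)
  }

  lo_zero <- nat_x[2] + dna_half + reach - dna_cx   # min shift for 0 overlap
  hi_zero <- x_pep[2] - dna_half + 3 - dna_cx       # keep contact w/ peptide
  out <- vector("list", n_decoys)
  zero_checked <- FALSE
  for (k in seq_len(n_decoys)) {
    tgt <- targets[k]
    phase <- stats::runif(1, -25, 25)
    if (tgt <= 0) {
      if (lo_zero > hi_zero) {
        stop("0-overlap decoys infeasible: peptide too short for this DNA")
      }
      dx <- stats::runif(1, lo_zero, hi_zero)
      dec <- move_dna(st, truth$dna_chains, dx = dx, phase = phase,
                      axis_y = mean(complex$dna$y))
      if (!zero_checked) {
        ov <- measure_overlap(dec)
        if (ov > 0) stop("0-overlap placement produced overlap ", ov)
        zero_checked <- TRUE
      }
    } else {
      # bisection between no shift (overlap 1) and the 0-overlap shift
      a <- 0; b <- max(lo_zero, 1)
      dec <- NULL
      for (it in 1:10) {
        mid <- (a + b) / 2
        cand <- move_dna(st, truth$dna_chains, dx = mid, phase = phase,
                         axis_y = mean(complex$dna$y))
        ov <- measure_overlap(cand)
        if (abs(ov - tgt) <= tol) { dec <- cand; dx <- mid; break }
        if (ov > tgt) a <- mid else b <- mid
      }
      if (is.null(dec)) {
        stop("could not reach overlap target ", tgt, " within tolerance ", tol)
      }
    }
    attr(dec, "dna_shift") <- dx
    out[[k]] <- dec
  }
  out
}
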