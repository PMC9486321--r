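# Interface identification, core/rim dissection, whole-interface statistics,
# spatial patch clustering and shortest-axis projection.

# which rows of a (and of b) lie within cutoff of any row of the other set;
# chunked to bound memory on large structures
cross_near <- function(a_xyz, b_xyz, cutoff) {
  na <- nrow(a_xyz); nb <- nrow(b_xyz)
  near_a <- logical(na); near_b <- logical(nb)
  cut2 <- cutoff^2
  b2 <- rowSums(b_xyz^2)
  chunk <- max(1L, floor(2e7 / max(nb, 1L)))
  for (start in seq(1L, na, by = chunk)) {
    idx <- start:min(start + chunk - 1L, na)
    d2 <- outer(rowSums(a_xyz[idx, , drop = FALSE]^2), b2, "+") -
      2 * a_xyz[idx, , drop = FALSE] %*% t(b_xyz)
    hit <- d2 <= cut2
    near_a[idx] <- rowSums(hit) > 0
    near_b <- near_b | colSums(hit) > 0
  }
  list(a = near_a, b = near_b)
}

new_interface <- function(atoms, residues, asa, params) {
  structure(list(atoms = atoms, residues = residues, asa = asa,
                 params = params),
            class = "pdi_interface")
}

residue_representatives <- function(component_structure, component) {
  rep_name <- if (component == "protein") "CA" else "C1'"
  heavy <- filter(component_structure, !.data$is_hydrogen)
  reps <- heavy |>
    filter(.data$atom_name == rep_name) |>
    distinct(across(all_of(RESIDUE_KEY)), .keep_all = TRUE) |>
    select(all_of(RESIDUE_KEY), rx = "x", ry = "y", rz = "z")
  missing <- anti_join(distinct(heavy, across(all_of(RESIDUE_KEY))), reps,
                       by = RESIDUE_KEY)
  if (nrow(missing) > 0) {
    centroids <- heavy |>
      semi_join(missing, by = RESIDUE_KEY) |>
      group_by(across(all_of(RESIDUE_KEY))) |>
      summarise(rx = mean(.data$x), ry = mean(.data$y), rz = mean(.data$z),
                .groups = "drop")
    reps <- bind_rows(reps, centroids)
  }
  reps
}

#' Identify the protein-DNA interface of a complex
#'
#' An atom is interfacial when it loses more than `asa_threshold` (default
#' 0.1 angstrom squared) of accessible surface area on complexation,
#' comparing the isolated component with the component in the complex
#' context (waters excluded from both). A residue or nucleotide is
#' interfacial when it owns at least one interface atom. Core/rim labels
#' are assigned by [dissect_core_rim()]: a residue with at least one fully
#' buried interface atom is core, the remainder rim.
#'
#' @param protein,dna the two components (see [split_components()]), with
#'   radii assigned.
#' @param asa_threshold buried-area threshold in angstrom squared.
#' @param probe_radius,n_sphere_points passed to [compute_asa()].
#' @param asa_protein_free,asa_dna_free optional precomputed isolated-
#'   component ASA maps (e.g. reused across rigid-body decoys of the same
#'   components); must match the quadrature settings.
#' @return a `pdi_interface` object: `$atoms` (per interface atom: identity,
#'   coordinates, free/complexed area, buried area, moiety, fully-buried
#'   flag), `$residues` (per interface residue: region, summed buried area,
#'   representative coordinates), `$asa` (the underlying maps and component
#'   surface totals) and `$params`.
#' @export
find_interface <- function(protein, dna, asa_threshold = 0.1,
                           probe_radius = 1.4, n_sphere_points = 960,
                           asa_protein_free = NULL, asa_dna_free = NULL) {
  if (nrow(protein) == 0 || nrow(dna) == 0) {
    stop("both components must contain atoms")
  }
  asa_p <- if (is.null(asa_protein_free)) {
    compute_asa(protein, probe_radius, n_sphere_points)
  } else asa_protein_free
  asa_d <- if (is.null(asa_dna_free)) {
    compute_asa(dna, probe_radius, n_sphere_points)
  } else asa_dna_free
  cplx <- new_structure(bind_rows(protein, dna))

  heavy <- filter(cplx, !.data$is_hydrogen)
  n_p <- nrow(asa_p)
  free_area <- c(asa_p$area, asa_d$area)
  if (length(free_area) != nrow(heavy)) {
    stop("free ASA maps do not match the components' heavy atoms")
  }
  # an atom's area can only change if an other-component atom lies within
  # occlusion reach; restrict the in-complex calculation to those atoms
  reach_cut <- max(heavy$vdw_radius) * 2 + 2 * probe_radius
  is_prot <- seq_len(nrow(heavy)) <= n_p
  near <- cross_near(cbind(heavy$x, heavy$y, heavy$z)[is_prot, , drop = FALSE],
                     cbind(heavy$x, heavy$y, heavy$z)[!is_prot, , drop = FALSE],
                     reach_cut)
  mask <- c(near$a, near$b)
  asa_c_area <- free_area
  if (any(mask)) {
    computed <- compute_asa(cplx, probe_radius, n_sphere_points,
                            subset = mask)
    asa_c_area[mask] <- computed$area[mask]
  }
  asa_c <- heavy |>
    select(all_of(ATOM_KEY)) |>
    mutate(area = asa_c_area)
  attr(asa_c, "probe_radius") <- probe_radius
  attr(asa_c, "n_sphere_points") <- n_sphere_points

  heavy_meta <- heavy |>
    select(all_of(ATOM_KEY), "component", "element", "polarity", "moiety",
           "x", "y", "z")

  dd <- bind_rows(
    delta_asa(asa_p, asa_c[seq_len(n_p), ]),
    delta_asa(asa_d, asa_c[-seq_len(n_p), ])
  ) |>
    left_join(heavy_meta, by = ATOM_KEY)

  atoms <- dd |>
    filter(.data$delta_area > asa_threshold) |>
    mutate(fully_buried = .data$area_complexed <= asa_threshold)

  if (nrow(atoms) == 0) {
    warning("no interface atoms found between the two components")
  }

  residues <- atoms |>
    group_by(.data$component, across(all_of(RESIDUE_KEY)), .data$residue_name) |>
    summarise(n_interface_atoms = n(),
              delta_area = sum(.data$delta_area),
              any_buried = any(.data$fully_buried),
              .groups = "drop") |>
    mutate(region = ifelse(.data$any_buried, "core", "rim")) |>
    select(-"any_buried")

  reps <- bind_rows(residue_representatives(protein, "protein"),
                    residue_representatives(dna, "dna"))
  residues <- left_join(residues, reps, by = RESIDUE_KEY)

  asa <- list(
    protein_free = asa_p, dna_free = asa_d, complex = asa_c,
    surface = c(protein = sum(asa_p$area), dna = sum(asa_d$area))
  )
  new_interface(atoms, residues, asa,
                params = list(asa_threshold = asa_threshold,
                              probe_radius = probe_radius,
                              n_sphere_points = n_sphere_points))
}

#' Dissect an interface into core and rim
#'
#' An interface atom is fully buried when its in-complex ASA is at or below
#' the buried-area threshold (a numerical-zero convention; exact zero is
#' fragile under quadrature). Residues owning at least one fully buried
#' atom are core, the rest rim.
#'
#' @param im a `pdi_interface`.
#' @param complex_asa optional replacement in-complex ASA map; defaults to
#'   the map stored in `im`.
#' @return `im` with `$atoms$fully_buried` and `$residues$region` updated.
#' @export
dissect_core_rim <- function(im, complex_asa = NULL) {
  atoms <- im$atoms
  if (!is.null(complex_asa)) {
    atoms <- atoms |>
      select(-"area_complexed") |>
      inner_join(rename(complex_asa, area_complexed = "area"), by = ATOM_KEY)
    if (nrow(atoms) != nrow(im$atoms)) {
      stop("complex_asa does not cover all interface atoms")
    }
  }
  atoms$fully_buried <- atoms$area_complexed <= im$params$asa_threshold
  regions <- atoms |>
    group_by(across(all_of(RESIDUE_KEY))) |>
    summarise(region = ifelse(any(.data$fully_buried), "core", "rim"),
              .groups = "drop")
  im$atoms <- atoms
  im$residues <- im$residues |>
    select(-"region") |>
    left_join(regions, by = RESIDUE_KEY)
  im
}

count_segments <- function(interface_resnos, max_gap = 4) {
  r <- sort(unique(interface_resnos))
  if (length(r) == 0) return(0L)
  sum(diff(r) > max_gap + 1) + 1L
}

#' Whole-interface physicochemical and geometric statistics
#'
#' Computes, per component and in total: interface area (sum of per-atom
#' buried area), interface/surface area ratio (denominator: the isolated
#' component's total ASA), atom and residue/nucleotide counts, fraction and
#' area of non-polar atoms, fraction of fully buried atoms, local density
#' (mean number of same-component interface atoms within 12 angstrom of each
#' interface atom), and the number of polypeptide segments (runs of
#' interface residues; residues separated by at most 4 consecutive
#' non-interface residues share a segment).
#'
#' @param im a `pdi_interface`.
#' @param density_radius neighbourhood radius for local density (angstrom).
#' @param segment_gap maximal run of non-interface residues bridged within
#'   one segment.
#' @return a tibble in table layout: one row per parameter with `protein`,
#'   `dna` and `total` columns; per-chain segment counts are attached as the
#'   `segments_by_chain` attribute.
#' @export
interface_statistics <- function(im, density_radius = 12, segment_gap = 4) {
  empty <- nrow(im$atoms) == 0
  comp_stat <- function(comp) {
    a <- filter(im$atoms, .data$component == comp)
    r <- filter(im$residues, .data$component == comp)
    if (nrow(a) == 0) {
      return(list(area = 0, ratio = 0, n_atoms = 0L, n_res = 0L,
                  f_nonpolar = NA_real_, np_area = 0, f_buried = NA_real_,
                  density = NA_real_))
    }
    xyz <- cbind(a$x, a$y, a$z)
    nb <- rowSums(as.matrix(dist(xyz)) <= density_radius) - 1
    list(
      area = sum(a$delta_area),
      ratio = sum(a$delta_area) /
        im$asa$surface[[if (comp == "protein") "protein" else "dna"]],
      n_atoms = nrow(a),
      n_res = nrow(r),
      f_nonpolar = mean(a$polarity == "nonpolar"),
      np_area = sum(a$delta_area[a$polarity == "nonpolar"]),
      f_buried = mean(a$fully_buried),
      density = mean(nb)
    )
  }
  p <- comp_stat("protein")
  d <- comp_stat("dna")
  all_a <- im$atoms

  seg_by_chain <- im$residues |>
    filter(.data$component == "protein") |>
    group_by(.data$chain) |>
    summarise(segments = count_segments(.data$residue_number, segment_gap),
              .groups = "drop")

  total <- list(
    area = p$area + d$area,
    ratio = (p$area + d$area) / sum(im$asa$surface),
    n_atoms = p$n_atoms + d$n_atoms,
    n_res = p$n_res + d$n_res,
    f_nonpolar = if (empty) NA_real_ else mean(all_a$polarity == "nonpolar"),
    np_area = p$np_area + d$np_area,
    f_buried = if (empty) NA_real_ else mean(all_a$fully_buried),
    segments = sum(seg_by_chain$segments)
  )

  out <- tibble(
    parameter = c("interface_area", "interface_vs_surface", "n_atoms",
                  "n_residues", "fraction_nonpolar", "nonpolar_area",
                  "fraction_fully_buried", "local_density", "n_segments"),
    protein = c(p$area, p$ratio, p$n_atoms, p$n_res, p$f_nonpolar, p$np_area,
                p$f_buried, p$density, total$segments),
    dna = c(d$area, d$ratio, d$n_atoms, d$n_res, d$f_nonpolar, d$np_area,
            d$f_buried, d$density, NA),
    total = c(total$area, total$ratio, total$n_atoms, total$n_res,
              total$f_nonpolar, total$np_area, total$f_buried, NA,
              total$segments)
  )
  attr(out, "segments_by_chain") <- seg_by_chain
  out
}

#' Cluster interface residues into spatial patches
#'
#' Single-linkage clustering of interface residues, using the C-alpha atom
#' (protein) or C1' atom (nucleotides) as the residue representative
#' (residue centroid when absent). Two residues are linked when their
#' representatives lie within `cutoff` angstrom; patches are the connected
#' components of that graph.
#'
#' @param im a `pdi_interface`.
#' @param cutoff linkage distance in angstrom (default 20).
#' @return `im` with a `patch` index column added to `$residues` and the
#'   cutoff recorded in `$params$patch_cutoff`.
#' @export
cluster_patches <- function(im, cutoff = 20) {
  res <- im$residues
  if (nrow(res) == 0) {
    im$residues$patch <- integer(0)
    im$params$patch_cutoff <- cutoff
    return(im)
  }
  if (nrow(res) == 1) {
    im$residues$patch <- 1L
  } else {
    hc <- hclust(dist(cbind(res$rx, res$ry, res$rz)), method = "single")
    raw <- cutree(hc, h = cutoff)
    # renumber patches by order of first appearance
    im$residues$patch <- as.integer(factor(raw, levels = unique(raw)))
  }
  im$params$patch_cutoff <- cutoff
  im
}

#' Project the interface down its shortest principal axis
#'
#' Principal axes are taken from the covariance matrix of the interface
#' atom coordinates (both components pooled); atoms are projected onto the
#' two largest-variance axes, i.e. viewed down the shortest axis. DNA atoms
#' keep their base/sugar/phosphate moiety labels so the two components can
#' be displayed together.
#'
#' @param im a `pdi_interface` with at least 3 non-collinear interface atoms.
#' @return a tibble with one row per interface atom: identity, component,
#'   moiety, region and projected coordinates `px`, `py`; eigenvectors and
#'   centroid are attached as attributes.
#' @export
project_interface <- function(im) {
  a <- im$atoms
  if (nrow(a) < 3) stop("need at least 3 interface atoms to project")
  xyz <- cbind(a$x, a$y, a$z)
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  ev <- eigen(cov(cen), symmetric = TRUE)
  if (ev$values[2] < 1e-8 * max(ev$values[1], 1)) {
    stop("interface atoms are collinear; projection is degenerate")
  }
  proj <- cen %*% ev$vectors[, 1:2]
  out <- a |>
    select("component", all_of(ATOM_KEY), "moiety") |>
    mutate(px = proj[, 1], py = proj[, 2]) |>
    left_join(select(im$residues, all_of(RESIDUE_KEY), "region"),
              by = RESIDUE_KEY)
  attr(out, "axes") <- ev$vectors
  attr(out, "eigenvalues") <- ev$values
  attr(out, "center") <- ctr
  out
}
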