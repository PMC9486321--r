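# Shared fixtures and independent oracles used across the test files.

# quick construction of an atom tibble (heavy atoms) with radii assigned
make_atoms <- function(df) {
  df$serial <- seq_len(nrow(df))
  if (!"altloc" %in% names(df)) df$altloc <- ""
  if (!"insert" %in% names(df)) df$insert <- ""
  df$occupancy <- 1
  df$element <- substr(gsub("[0-9']", "", df$atom_name), 1, 1)
  df$is_hydrogen <- df$element %in% c("H", "D")
  if (!"component" %in% names(df)) {
    df$component <- ifelse(
      df$residue_name %in% c("HOH", "WAT", "DOD"), "water",
      ifelse(df$residue_name %in% c("DA", "DC", "DG", "DT"), "dna",
             "protein"))
  }
  df$polarity <- ifelse(df$element %in% c("C", "S"), "nonpolar", "polar")
  df$moiety <- NA_character_
  df$vdw_radius <- NA_real_
  st <- dnaface:::new_structure(tibble::as_tibble(df))
  assign_radii(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent SASA oracle: random-direction quadrature (different point
# construction from the implementation's golden spiral), plain R
sasa_oracle <- function(coords, radii, probe = 1.4, n_points = 1e5,
                        seed = 99) {
  set.seed(seed)
  z <- runif(n_points, -1, 1)
  phi <- runif(n_points, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  n <- nrow(coords)
  ex <- radii + probe
  vapply(seq_len(n), function(i) {
    sp <- sweep(pts * ex[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      free <- free & d2 >= ex[j]^2
      if (!any(free)) break
    }
    4 * pi * ex[i]^2 * mean(free)
  }, numeric(1))
}

# union-find oracle for single-linkage clustering at a distance cutoff
union_find_clusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# minimal pdi_interface for geometry-only operations
fake_interface <- function(xyz, component = "protein",
                           residue_number = seq_len(nrow(xyz))) {
  atoms <- tibble::tibble(
    chain = "A", residue_number = residue_number, insert = "",
    residue_name = "ALA", atom_name = "CA",
    area_free = 10, area_complexed = 5, delta_area = 5,
    component = component, element = "C", polarity = "nonpolar",
    moiety = NA_character_,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], fully_buried = FALSE)
  residues <- atoms |>
    dplyr::distinct(component, chain, residue_number, insert, residue_name) |>
    dplyr::mutate(n_interface_atoms = 1L, delta_area = 5, region = "rim",
                  rx = xyz[, 1], ry = xyz[, 2], rz = xyz[, 3])
  structure(list(atoms = atoms, residues = residues,
                 asa = list(surface = c(protein = 100, dna = 100)),
                 params = list(asa_threshold = 0.1, probe_radius = 1.4,
                               n_sphere_points = 960)),
            class = "pdi_interface")
}

# one default toy complex reused by several files (built once per run)
toy_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_complex(seed = 1)
    cache
  }
})

pdb_min_line <- local({
  counter <- 0L
  function(atom = "CA", res = "ALA", chain = "A", resno = 1,
           x = 0, y = 0, z = 0, rec = "ATOM  ", element = " C") {
    counter <<- counter + 1L
    sprintf(
      "%s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %s",
      rec, counter, atom, res, chain, resno, x, y, z, element)
  }
})
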