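# Full-pipeline orchestration: one call dissects a complex into the
# complete interface report; writers emit the .int/.ent/.ncons/.hbd/.water/
# .cont/.proj text files.

#' Dissect a protein-DNA interface end to end
#'
#' Runs the whole pipeline on one complex: parse (if given a path), assign
#' radii, split components, identify the interface and its core/rim,
#' cluster patches, compute whole-interface statistics, detect hydrogen
#' bonds, classify interface waters, count potential donors (Dp), score the
#' composition (Rp), classify interface secondary structure, project the
#' interface down its shortest axis and - when an alignment is supplied -
#' compute the conservation profile and Ncons. Without an alignment the
#' conservation outputs are absent and the rest of the report is produced.
#' A run is deterministic for a fixed configuration.
#'
#' @param pdb a `pdi_structure` or a path to a PDB file.
#' @param protein_chains,dna_chains chain identifier vectors.
#' @param msa optional alignment: a `pdi_alignment`, a path to an aligned
#'   FASTA file, or FASTA text.
#' @param msa_chain protein chain scored for conservation (default: first
#'   protein chain).
#' @param asa_threshold interface buried-area threshold (angstrom squared).
#' @param donor_min_asa Dp accessibility threshold (angstrom squared).
#' @param water_cutoff interface-water contact distance (angstrom).
#' @param cluster_distance patch linkage distance (angstrom).
#' @param min_identity close-homolog identity cutoff (fraction).
#' @param hb_max_da hydrogen-bond donor-acceptor distance cutoff (angstrom).
#' @param contact_cutoff residue-nucleotide contact distance (angstrom).
#' @param propensity propensity table for Rp.
#' @param probe_radius,n_sphere_points ASA quadrature settings.
#' @return a `pdi_report` list: `summary` (the interface parameter table in
#'   protein/DNA/total layout), `interface`, `stats`, `hbonds`, `waters`,
#'   `donors`, `projection`, `contacts`, `secondary_structure`, `entropy`
#'   (or `NULL`), components and the configuration.
#' @export
dissect_complex <- function(pdb, protein_chains, dna_chains, msa = NULL,
                            msa_chain = NULL, asa_threshold = 0.1,
                            donor_min_asa = 10, water_cutoff = 4.5,
                            cluster_distance = 20, min_identity = 0.30,
                            hb_max_da = 3.35, contact_cutoff = 4.5,
                            propensity = propensity_table_synthetic(),
                            probe_radius = 1.4, n_sphere_points = 960) {
  st <- if (is.character(pdb)) read_structure(pdb) else pdb
  if (anyNA(st$vdw_radius[!st$is_hydrogen])) st <- assign_radii(st)
  comps <- split_components(st, protein_chains, dna_chains)

  im <- find_interface(comps$protein, comps$dna,
                       asa_threshold = asa_threshold,
                       probe_radius = probe_radius,
                       n_sphere_points = n_sphere_points)
  im <- cluster_patches(im, cutoff = cluster_distance)
  stats_tbl <- interface_statistics(im)

  with_waters <- new_structure(bind_rows(comps$protein, comps$dna,
                                         comps$waters))
  hbonds <- detect_hbonds(with_waters, max_da = hb_max_da)
  waters <- classify_interface_waters(with_waters, hbonds,
                                      contact_cutoff = water_cutoff)

  donors <- count_potential_donors(
    comps$protein, asa = im$asa$protein_free,
    residues = filter(im$residues, .data$component == "protein"),
    min_asa = donor_min_asa)
  rp <- residue_propensity_score(interface_composition(im), propensity)
  ss <- classify_secondary_structure(comps$protein, im)
  projection <- if (nrow(im$atoms) >= 3) project_interface(im) else NULL
  contacts <- contact_map(comps$protein, comps$dna, cutoff = contact_cutoff)

  entropy <- NULL
  if (!is.null(msa)) {
    aln <- if (inherits(msa, "pdi_alignment")) msa else read_msa(msa)
    aln <- filter_homologs(aln, min_identity = min_identity)
    entropy <- interface_entropy_profile(aln, im, comps$protein,
                                         chain = msa_chain)
  }

  wc <- waters$counts
  summary <- bind_rows(
    stats_tbl,
    tibble(parameter = "residue_propensity_score",
           protein = rp, dna = NA, total = NA),
    tibble(parameter = "n_potential_donors",
           protein = donors$dp, dna = NA, total = NA),
    tibble(parameter = "n_direct_hbonds",
           protein = NA, dna = NA, total = wc$n_direct_hbonds),
    tibble(parameter = "n_bridging_hb_interactions",
           protein = NA, dna = NA, total = wc$n_bridging_hb),
    tibble(parameter = "n_hbs_water_single_component",
           protein = wc$n_hb_water_protein_only,
           dna = wc$n_hb_water_dna_only,
           total = wc$n_hb_water_protein_only + wc$n_hb_water_dna_only),
    tibble(parameter = "n_interface_waters",
           protein = NA, dna = NA, total = wc$n_interface_waters),
    tibble(parameter = "n_bridging_waters",
           protein = NA, dna = NA, total = wc$n_bridging),
    tibble(parameter = "n_waters_single_component",
           protein = wc$n_protein_only, dna = wc$n_dna_only,
           total = wc$n_single_sided),
    tibble(parameter = "n_waters_water_only",
           protein = NA, dna = NA, total = wc$n_water_only)
  )

  structure(list(
    summary = summary, interface = im, stats = stats_tbl, hbonds = hbonds,
    waters = waters, donors = donors, rp = rp,
    secondary_structure = ss, projection = projection, contacts = contacts,
    entropy = entropy, components = comps,
    config = list(protein_chains = protein_chains, dna_chains = dna_chains,
                  asa_threshold = asa_threshold,
                  donor_min_asa = donor_min_asa, water_cutoff = water_cutoff,
                  cluster_distance = cluster_distance,
                  min_identity = min_identity, hb_max_da = hb_max_da,
                  contact_cutoff = contact_cutoff,
                  probe_radius = probe_radius,
                  n_sphere_points = n_sphere_points)
  ), class = "pdi_report")
}

#' @export
print.pdi_report <- function(x, ...) {
  cat("<pdi_report> interface of", paste(x$config$protein_chains,
                                         collapse = ","),
      "(protein) vs", paste(x$config$dna_chains, collapse = ","), "(DNA)\n")
  cat("  secondary-structure class:", x$secondary_structure$class, "\n\n")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Residue-nucleotide contact map
#'
#' Lists every (protein residue, nucleotide) pair with at least one
#' heavy-atom pair within `cutoff` angstrom; the relation is symmetric, so
#' the transposed map is obtained by reordering columns.
#'
#' @param protein,dna the two components.
#' @param cutoff heavy-atom contact distance (angstrom).
#' @return a tibble: protein residue identity, nucleotide identity, minimal
#'   atom distance and number of contacting atom pairs.
#' @export
contact_map <- function(protein, dna, cutoff = 4.5) {
  p <- filter(protein, !.data$is_hydrogen)
  d <- filter(dna, !.data$is_hydrogen)
  if (nrow(p) == 0 || nrow(d) == 0) return(empty_contact_tibble())
  dd <- sqrt(pmax(outer(rowSums(cbind(p$x, p$y, p$z)^2),
                        rowSums(cbind(d$x, d$y, d$z)^2), "+") -
                    2 * cbind(p$x, p$y, p$z) %*% t(cbind(d$x, d$y, d$z)), 0))
  hit <- which(dd <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_contact_tibble())
  tibble(
    protein_chain = p$chain[hit[, 1]],
    protein_residue_number = p$residue_number[hit[, 1]],
    protein_insert = p$insert[hit[, 1]],
    protein_residue_name = p$residue_name[hit[, 1]],
    dna_chain = d$chain[hit[, 2]],
    dna_residue_number = d$residue_number[hit[, 2]],
    dna_insert = d$insert[hit[, 2]],
    dna_residue_name = d$residue_name[hit[, 2]],
    distance = dd[hit]
  ) |>
    group_by(across(-"distance")) |>
    summarise(min_distance = min(.data$distance), n_atom_pairs = n(),
              .groups = "drop") |>
    arrange(.data$protein_chain, .data$protein_residue_number,
            .data$dna_chain, .data$dna_residue_number)
}

empty_contact_tibble <- function() {
  tibble(protein_chain = character(), protein_residue_number = integer(),
         protein_insert = character(), protein_residue_name = character(),
         dna_chain = character(), dna_residue_number = integer(),
         dna_insert = character(), dna_residue_name = character(),
         min_distance = numeric(), n_atom_pairs = integer())
}

fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}

write_tsv_report <- function(df, path, header) {
  lines <- c(paste0("# ", header),
             paste(colnames(df), collapse = "\t"))
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
}

#' Write the report's downloadable text files
#'
#' Emits the tab-delimited output files next to each other in `dir`:
#' `<prefix>.int` (interface residues/nucleotides with region, buried area
#' and patch), `.ent` (interface residue entropies), `.ncons` (the subset
#' below the interface mean), `.hbd` (potential donor atoms with areas),
#' `.water` (interface waters with categories and bonded partners),
#' `.cont` (residue-nucleotide contacts, both directions) and `.proj`
#' (shortest-axis projection coordinates). All files are UTF-8 with a
#' single commented header line; areas carry 1 decimal, entropies 3.
#'
#' @param report a `pdi_report`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return the written paths, invisibly.
#' @export
write_report_files <- function(report, dir, prefix = "complex") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  pth <- function(ext) file.path(dir, paste0(prefix, ".", ext))

  res <- report$interface$residues |>
    mutate(delta_area = fmt_num(.data$delta_area, 1)) |>
    select("chain", "residue_number", "insert", "residue_name", "component",
           "region", "delta_area", any_of("patch"))
  write_tsv_report(res, pth("int"),
                   "interface residues and nucleotides; areas in A^2")
  paths <- c(paths, pth("int"))

  if (!is.null(report$entropy)) {
    ent <- report$entropy |>
      mutate(s = fmt_num(.data$s, 3)) |>
      select("chain", "residue_number", "insert", "residue_name", "s",
             "region")
    write_tsv_report(ent, pth("ent"),
                     "Shannon entropies (nats) of interface residues")
    ncons <- report$entropy |>
      filter(.data$conserved) |>
      mutate(s = fmt_num(.data$s, 3)) |>
      select("chain", "residue_number", "insert", "residue_name", "s",
             "region")
    write_tsv_report(ncons, pth("ncons"),
                     "interface residues with entropy below the interface mean")
    paths <- c(paths, pth("ent"), pth("ncons"))
  }

  hbd <- report$donors$donors |>
    mutate(area = fmt_num(.data$area, 1)) |>
    select("chain", "residue_number", "insert", "residue_name", "atom_name",
           "area")
  write_tsv_report(hbd, pth("hbd"),
                   "potential hydrogen-bond donor atoms with ASA >= threshold")
  paths <- c(paths, pth("hbd"))

  hb <- report$hbonds
  wpart <- bind_rows(
    hb |> filter(.data$donor_component == "water") |>
      mutate(water = water_key(.data$donor_chain, .data$donor_residue_number,
                               .data$donor_insert),
             partner = paste0(.data$acceptor_chain, ":",
                              .data$acceptor_residue_number,
                              .data$acceptor_residue_name, ":",
                              .data$acceptor_atom, "@",
                              fmt_num(.data$distance, 2))) |>
      select("water", "partner"),
    hb |> filter(.data$acceptor_component == "water") |>
      mutate(water = water_key(.data$acceptor_chain,
                               .data$acceptor_residue_number,
                               .data$acceptor_insert),
             partner = paste0(.data$donor_chain, ":",
                              .data$donor_residue_number,
                              .data$donor_residue_name, ":",
                              .data$donor_atom, "@",
                              fmt_num(.data$distance, 2))) |>
      select("water", "partner")
  ) |>
    group_by(.data$water) |>
    summarise(partners = paste(sort(.data$partner), collapse = ";"),
              .groups = "drop")
  wat <- report$waters$waters |>
    left_join(wpart, by = "water") |>
    mutate(partners = ifelse(is.na(.data$partners), "", .data$partners)) |>
    select("water", "category", "n_hb_protein", "n_hb_dna", "n_hb_water",
           "partners")
  write_tsv_report(wat, pth("water"),
                   "interface waters and their hydrogen-bond partners")
  paths <- c(paths, pth("water"))

  cont <- report$contacts |>
    mutate(min_distance = fmt_num(.data$min_distance, 2))
  cont_rev <- cont |>
    select("dna_chain", "dna_residue_number", "dna_insert",
           "dna_residue_name", "protein_chain", "protein_residue_number",
           "protein_insert", "protein_residue_name", "min_distance",
           "n_atom_pairs") |>
    arrange(.data$dna_chain, .data$dna_residue_number,
            .data$protein_chain, .data$protein_residue_number)
  write_tsv_report(cont, pth("cont"),
                   "nucleotides in contact with each protein residue")
  write_tsv_report(cont_rev, pth("rcont"),
                   "protein residues in contact with each nucleotide")
  paths <- c(paths, pth("cont"), pth("rcont"))

  if (!is.null(report$projection)) {
    proj <- report$projection |>
      mutate(px = fmt_num(.data$px, 2), py = fmt_num(.data$py, 2)) |>
      select("px", "py", "component", "chain", "residue_number", "insert",
             "residue_name", "atom_name", "region", "moiety")
    if (!is.null(report$entropy)) {
      proj <- proj |>
        left_join(report$entropy |>
                    mutate(s = fmt_num(.data$s, 3)) |>
                    select(all_of(RESIDUE_KEY), "s"),
                  by = RESIDUE_KEY)
    }
    write_tsv_report(proj, pth("proj"),
                     "interface projected down its shortest principal axis")
    paths <- c(paths, pth("proj"))
  }
  invisible(paths)
}
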