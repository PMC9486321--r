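# Hydrogen-bond detection (heavy-atom geometric criteria) and interface
# water classification.

# Donor and acceptor dictionaries for the 20 amino acids, the four
# deoxynucleotides and water. Backbone amide N donates (except proline);
# backbone carbonyl O accepts. Hydroxyls donate and accept.
hb_dict_protein <- function() {
  don <- list(
    ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
    ASN = "ND2", GLN = "NE2", TRP = "NE1", SER = "OG", THR = "OG1",
    TYR = "OH", CYS = "SG"
  )
  acc <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
    HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
  )
  aa <- names(AA3)
  donors <- bind_rows(
    tibble(residue_name = setdiff(aa, "PRO"), atom_name = "N"),
    purrr::imap_dfr(don, ~ tibble(residue_name = .y, atom_name = .x))
  )
  acceptors <- bind_rows(
    tibble(residue_name = aa, atom_name = "O"),
    tibble(residue_name = aa, atom_name = "OXT"),
    purrr::imap_dfr(acc, ~ tibble(residue_name = .y, atom_name = .x))
  )
  list(donors = donors, acceptors = acceptors)
}

hb_dict_dna <- function() {
  don <- list(DA = "N6", DC = "N4", DG = c("N1", "N2"), DT = "N3")
  acc <- list(
    DA = c("N1", "N3", "N7"), DG = c("N3", "N7", "O6"),
    DC = c("O2", "N3"), DT = c("O2", "O4"), DU = c("O2", "O4")
  )
  backbone_acc <- c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'")
  nts <- DNA_NAMES
  strip_d <- function(x) ifelse(nchar(x) == 2, substr(x, 2, 2), x)
  expand <- function(lst) {
    purrr::imap_dfr(lst, ~ tibble(residue_name = .y, atom_name = .x)) |>
      (\(d) bind_rows(d, mutate(d, residue_name = strip_d(.data$residue_name))))()
  }
  donors <- expand(don)
  acceptors <- bind_rows(
    expand(acc),
    tidyr::expand_grid(residue_name = nts, atom_name = backbone_acc)
  )
  list(donors = distinct(donors), acceptors = distinct(acceptors))
}

#' Hydrogen-bond donor/acceptor dictionary
#'
#' @return a list with `donors` and `acceptors` tibbles
#'   (`residue_name`, `atom_name`) covering the 20 amino acids, the
#'   deoxynucleotides and water (water oxygen is both donor and acceptor).
#' @export
hb_dictionary <- function() {
  p <- hb_dict_protein()
  d <- hb_dict_dna()
  w_don <- tidyr::expand_grid(residue_name = WATER_NAMES, atom_name = "O")
  list(donors = bind_rows(p$donors, d$donors, w_don),
       acceptors = bind_rows(p$acceptors, d$acceptors, w_don))
}

# nearest covalently bonded heavy atom within the same residue (for the
# donor-angle test); NULL when none within bonding distance
donor_antecedents <- function(atoms, donors_idx, bond_max = 1.8) {
  ante <- rep(NA_integer_, length(donors_idx))
  key <- paste(atoms$chain, atoms$residue_number, atoms$insert)
  for (i in seq_along(donors_idx)) {
    di <- donors_idx[i]
    same <- which(key == key[di])
    same <- same[same != di & !atoms$is_hydrogen[same]]
    if (length(same) == 0) next
    d2 <- (atoms$x[same] - atoms$x[di])^2 + (atoms$y[same] - atoms$y[di])^2 +
      (atoms$z[same] - atoms$z[di])^2
    j <- which.min(d2)
    if (d2[j] <= bond_max^2) ante[i] <- same[j]
  }
  ante
}

#' Detect hydrogen bonds in a complex
#'
#' Heavy-atom geometric criterion: a donor and an acceptor from the bundled
#' dictionaries form a hydrogen bond when their distance is at most
#' `max_da` (default 3.35 angstrom) and, where the donor has a covalently
#' bonded antecedent atom, the antecedent-donor-acceptor angle is at least
#' `min_donor_angle` degrees. Water oxygens act as both donor and acceptor
#' (no angle test). Each unordered atom pair is reported once; pairs within
#' one residue are excluded. Bonds are categorised by the components of the
#' two partners: `protein-dna`, `protein-water`, `dna-water`, `water-water`
#' or `intra` (within one component).
#'
#' @param complex_structure a `pdi_structure` containing protein, DNA and
#'   (optionally) water atoms.
#' @param max_da donor-acceptor distance cutoff (angstrom).
#' @param min_donor_angle minimal antecedent-donor-acceptor angle (degrees).
#' @return a tibble with one row per hydrogen bond: donor and acceptor atom
#'   identities, distance, donor angle (NA when not computable) and category.
#' @export
detect_hbonds <- function(complex_structure, max_da = 3.35,
                          min_donor_angle = 90) {
  atoms <- filter(complex_structure, !.data$is_hydrogen)
  dict <- hb_dictionary()

  tag <- function(df) paste(df$residue_name, df$atom_name)
  don_idx <- which(tag(atoms) %in% tag(dict$donors))
  acc_idx <- which(tag(atoms) %in% tag(dict$acceptors))
  if (length(don_idx) == 0 || length(acc_idx) == 0) {
    return(empty_hbond_tibble())
  }

  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  res_key <- paste(atoms$chain, atoms$residue_number, atoms$insert)

  # candidate pairs within the distance cutoff
  pairs <- NULL
  for (chunk in split(don_idx, ceiling(seq_along(don_idx) / 500))) {
    dmat <- sqrt(pmax(outer(rowSums(xyz[chunk, , drop = FALSE]^2),
                            rowSums(xyz[acc_idx, , drop = FALSE]^2), "+") -
                        2 * xyz[chunk, , drop = FALSE] %*%
                        t(xyz[acc_idx, , drop = FALSE]), 0))
    hit <- which(dmat <= max_da, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      pairs <- rbind(pairs, cbind(chunk[hit[, 1]], acc_idx[hit[, 2]],
                                  dmat[hit]))
    }
  }
  if (is.null(pairs) || nrow(pairs) == 0) return(empty_hbond_tibble())

  keep <- res_key[pairs[, 1]] != res_key[pairs[, 2]]
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty_hbond_tibble())

  # donor-angle test where an antecedent exists
  d_i <- pairs[, 1]
  a_i <- pairs[, 2]
  ante <- donor_antecedents(atoms, d_i)
  angle <- rep(NA_real_, nrow(pairs))
  has_ante <- !is.na(ante)
  if (any(has_ante)) {
    v1 <- xyz[ante[has_ante], , drop = FALSE] - xyz[d_i[has_ante], , drop = FALSE]
    v2 <- xyz[a_i[has_ante], , drop = FALSE] - xyz[d_i[has_ante], , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    angle[has_ante] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  }
  ok <- is.na(angle) | angle >= min_donor_angle
  pairs <- pairs[ok, , drop = FALSE]
  angle <- angle[ok]
  if (nrow(pairs) == 0) return(empty_hbond_tibble())
  d_i <- pairs[, 1]
  a_i <- pairs[, 2]

  comp_of <- atoms$component
  cat_of <- function(c1, c2) {
    dplyr::case_when(
      c1 == c2 & c1 == "water" ~ "water-water",
      c1 == c2 ~ "intra",
      (c1 == "protein" & c2 == "dna") | (c1 == "dna" & c2 == "protein") ~ "protein-dna",
      (c1 == "protein" & c2 == "water") | (c1 == "water" & c2 == "protein") ~ "protein-water",
      (c1 == "dna" & c2 == "water") | (c1 == "water" & c2 == "dna") ~ "dna-water",
      TRUE ~ "other"
    )
  }

  out <- tibble(
    donor_chain = atoms$chain[d_i],
    donor_residue_number = atoms$residue_number[d_i],
    donor_insert = atoms$insert[d_i],
    donor_residue_name = atoms$residue_name[d_i],
    donor_atom = atoms$atom_name[d_i],
    donor_component = comp_of[d_i],
    acceptor_chain = atoms$chain[a_i],
    acceptor_residue_number = atoms$residue_number[a_i],
    acceptor_insert = atoms$insert[a_i],
    acceptor_residue_name = atoms$residue_name[a_i],
    acceptor_atom = atoms$atom_name[a_i],
    acceptor_component = comp_of[a_i],
    distance = pairs[, 3],
    donor_angle = angle,
    category = cat_of(comp_of[d_i], comp_of[a_i])
  )

  # report each unordered atom pair once (a hydroxyl pair can qualify in
  # both directions); keep the first listing
  pair_id <- purrr::map2_chr(
    paste(atoms$serial[d_i]), paste(atoms$serial[a_i]),
    ~ paste(sort(c(.x, .y)), collapse = "_"))
  out[!duplicated(pair_id), ]
}

empty_hbond_tibble <- function() {
  tibble(
    donor_chain = character(), donor_residue_number = integer(),
    donor_insert = character(), donor_residue_name = character(),
    donor_atom = character(), donor_component = character(),
    acceptor_chain = character(), acceptor_residue_number = integer(),
    acceptor_insert = character(), acceptor_residue_name = character(),
    acceptor_atom = character(), acceptor_component = character(),
    distance = numeric(), donor_angle = numeric(), category = character()
  )
}

water_key <- function(chain, residue_number, insert) {
  paste0(chain, ":", residue_number, insert)
}

#' Classify interface waters
#'
#' An interface water is a crystallographic water whose oxygen lies within
#' `contact_cutoff` (default 4.5 angstrom) of at least one protein heavy
#' atom and at least one DNA heavy atom. Each interface water is assigned
#' one category from its hydrogen bonds: `bridging` (bonded to both
#' components), `protein-only` or `dna-only` (bonded to exactly one
#' component, water bonds allowed), `water-only` (bonded only to other
#' interface waters) or `none`. The bridging hydrogen-bond interaction
#' count is the number of distinct protein-DNA atom pairs connected through
#' one water, i.e. the per-water product of protein-side and DNA-side bond
#' counts, summed over bridging waters.
#'
#' @param complex_structure the full complex including waters.
#' @param hbonds hydrogen bonds from [detect_hbonds()] on the same structure.
#' @param contact_cutoff heavy-atom contact distance (angstrom).
#' @return a list with `waters` (one row per interface water: category and
#'   per-partner bond counts) and `counts` (a one-row summary tibble).
#' @export
classify_interface_waters <- function(complex_structure, hbonds,
                                      contact_cutoff = 4.5) {
  atoms <- filter(complex_structure, !.data$is_hydrogen)
  w <- filter(atoms, .data$component == "water", .data$atom_name == "O" |
                .data$element == "O")
  p <- filter(atoms, .data$component == "protein")
  d <- filter(atoms, .data$component == "dna")

  near_any <- function(w, comp, cutoff) {
    if (nrow(w) == 0 || nrow(comp) == 0) return(rep(FALSE, nrow(w)))
    cxyz <- cbind(comp$x, comp$y, comp$z)
    purrr::map_lgl(seq_len(nrow(w)), function(i) {
      dx <- cxyz[, 1] - w$x[i]; dy <- cxyz[, 2] - w$y[i]; dz <- cxyz[, 3] - w$z[i]
      any(dx * dx + dy * dy + dz * dz <= cutoff^2)
    })
  }
  iface <- near_any(w, p, contact_cutoff) & near_any(w, d, contact_cutoff)
  iw <- w[iface, , drop = FALSE]
  iw_key <- water_key(iw$chain, iw$residue_number, iw$insert)

  # hydrogen-bond partners per water
  hb_w_d <- filter(hbonds, .data$donor_component == "water")
  hb_w_a <- filter(hbonds, .data$acceptor_component == "water")
  partner <- bind_rows(
    tibble(water = water_key(hb_w_d$donor_chain, hb_w_d$donor_residue_number,
                             hb_w_d$donor_insert),
           partner_component = hb_w_d$acceptor_component,
           partner = water_key(hb_w_d$acceptor_chain,
                               hb_w_d$acceptor_residue_number,
                               hb_w_d$acceptor_insert)),
    tibble(water = water_key(hb_w_a$acceptor_chain,
                             hb_w_a$acceptor_residue_number,
                             hb_w_a$acceptor_insert),
           partner_component = hb_w_a$donor_component,
           partner = water_key(hb_w_a$donor_chain, hb_w_a$donor_residue_number,
                               hb_w_a$donor_insert))
  ) |>
    filter(.data$water %in% iw_key)

  per_water <- partner |>
    group_by(.data$water) |>
    summarise(
      n_hb_protein = sum(.data$partner_component == "protein"),
      n_hb_dna = sum(.data$partner_component == "dna"),
      n_hb_water = sum(.data$partner_component == "water" &
                         .data$partner %in% iw_key),
      .groups = "drop")

  waters <- tibble(water = iw_key, chain = iw$chain,
                   residue_number = iw$residue_number, insert = iw$insert) |>
    left_join(per_water, by = "water") |>
    mutate(across(c("n_hb_protein", "n_hb_dna", "n_hb_water"),
                  ~ ifelse(is.na(.x), 0L, .x))) |>
    mutate(category = dplyr::case_when(
      .data$n_hb_protein > 0 & .data$n_hb_dna > 0 ~ "bridging",
      .data$n_hb_protein > 0 ~ "protein-only",
      .data$n_hb_dna > 0 ~ "dna-only",
      .data$n_hb_water > 0 ~ "water-only",
      TRUE ~ "none"
    ))

  bridging <- filter(waters, .data$category == "bridging")
  counts <- tibble(
    n_interface_waters = nrow(waters),
    n_bridging = nrow(bridging),
    n_protein_only = sum(waters$category == "protein-only"),
    n_dna_only = sum(waters$category == "dna-only"),
    n_single_sided = sum(waters$category %in% c("protein-only", "dna-only")),
    n_water_only = sum(waters$category == "water-only"),
    n_none = sum(waters$category == "none"),
    n_direct_hbonds = sum(hbonds$category == "protein-dna"),
    n_bridging_hb = sum(bridging$n_hb_protein * bridging$n_hb_dna),
    n_hb_water_protein_only = sum(
      waters$n_hb_protein[waters$category == "protein-only"]),
    n_hb_water_dna_only = sum(waters$n_hb_dna[waters$category == "dna-only"])
  )
  list(waters = waters, counts = counts)
}
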