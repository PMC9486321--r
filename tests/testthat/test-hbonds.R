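mini_pair <- function(d) {
  # Ser OG (with CB antecedent) facing a DNA OP1 at distance d
  make_atoms(tibble::tibble(
    atom_name = c("CB", "OG", "OP1", "P"),
    residue_name = c("SER", "SER", "DG", "DG"),
    chain = c("A", "A", "B", "B"),
    residue_number = c(1, 1, 5, 5),
    x = c(-1.5, 0, d, d + 1.5), y = 0, z = 0))
}

test_that("a donor-acceptor pair within the cutoff forms one protein-DNA bond", {
  hb <- detect_hbonds(mini_pair(2.9))
  hb_pd <- dplyr::filter(hb, category == "protein-dna")
  expect_equal(nrow(hb_pd), 1)
  expect_equal(hb_pd$donor_atom, "OG")
  expect_equal(hb_pd$acceptor_atom, "OP1")
  expect_equal(hb_pd$distance, 2.9, tolerance = 1e-6)
  expect_gte(hb_pd$donor_angle, 90)
})

test_that("pairs beyond the distance cutoff are not bonded", {
  hb <- detect_hbonds(mini_pair(4.5))
  expect_equal(nrow(dplyr::filter(hb, category == "protein-dna")), 0)
})

test_that("the donor-angle criterion rejects backward geometry", {
  # acceptor on the same side as the antecedent: angle ~0
  st <- make_atoms(tibble::tibble(
    atom_name = c("CB", "OG", "OP1", "P"),
    residue_name = c("SER", "SER", "DG", "DG"),
    chain = c("A", "A", "B", "B"),
    residue_number = c(1, 1, 5, 5),
    x = c(-1.5, 0, -3.0, -4.5), y = c(0, 0, 0.5, 0.5), z = 0))
  hb <- detect_hbonds(st)
  expect_equal(nrow(dplyr::filter(hb, category == "protein-dna")), 0)
})

test_that("each unordered atom pair is reported once", {
  # two hydroxyls: both directions qualify, one bond reported
  st <- make_atoms(tibble::tibble(
    atom_name = c("CB", "OG", "CB", "OG"),
    residue_name = "SER", chain = "A",
    residue_number = c(1, 1, 2, 2),
    x = c(-1.5, 0, 4.3, 2.8), y = 0, z = 0))
  hb <- detect_hbonds(st)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$category, "intra")
})

test_that("planted bridging waters are classified exactly", {
  cx <- make_toy_complex(n_bridging_waters = 2, n_far_waters = 2, seed = 4)
  hb <- detect_hbonds(cx$structure)
  wc <- classify_interface_waters(cx$structure, hb)
  expect_equal(wc$counts$n_bridging, 2)
  bridging <- wc$waters$residue_number[wc$waters$category == "bridging"]
  expect_setequal(bridging, cx$truth$bridging_waters)
  # far waters are not interface waters at all
  expect_false(any(cx$truth$far_waters %in% wc$waters$residue_number))
})

test_that("water categories partition the interface waters", {
  cx <- make_toy_complex(n_bridging_waters = 2, n_far_waters = 1, seed = 8)
  hb <- detect_hbonds(cx$structure)
  wc <- classify_interface_waters(cx$structure, hb)
  n <- wc$counts
  expect_equal(n$n_bridging + n$n_single_sided + n$n_water_only + n$n_none,
               n$n_interface_waters)
  expect_equal(nrow(wc$waters), n$n_interface_waters)
  expect_true(all(table(wc$waters$water) == 1))
})

test_that("interface-water count is monotone in the contact cutoff", {
  cx <- make_toy_complex(n_bridging_waters = 2, n_far_waters = 2, seed = 4)
  hb <- detect_hbonds(cx$structure)
  counts <- vapply(c(3, 4.5, 6, 15), function(cut) {
    classify_interface_waters(cx$structure, hb,
                              contact_cutoff = cut)$counts$n_interface_waters
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("bridging waters carry at least two bonds and interactions >= waters", {
  cx <- make_toy_complex(n_bridging_waters = 2, seed = 4)
  hb <- detect_hbonds(cx$structure)
  wc <- classify_interface_waters(cx$structure, hb)
  br <- dplyr::filter(wc$waters, category == "bridging")
  expect_true(all(br$n_hb_protein + br$n_hb_dna >= 2))
  expect_gte(wc$counts$n_bridging_hb, wc$counts$n_bridging)
})

test_that("a mirrored complex yields the same number of bonds", {
  cx <- toy_default()
  hb1 <- detect_hbonds(cx$structure)
  mir <- cx$structure
  mir$z <- -mir$z
  hb2 <- detect_hbonds(mir)
  expect_equal(nrow(hb1), nrow(hb2))
  expect_equal(sort(table(hb1$category)), sort(table(hb2$category)))
})
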