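test_that("Rp is the exact composition-weighted sum and is linear", {
  tbl <- propensity_table_synthetic()
  expect_equal(residue_propensity_score(tibble::tibble(
    residue_name = character(), n = integer())), 0)
  expect_equal(residue_propensity_score(
    tibble::tibble(residue_name = "ARG", n = 2),
    tibble::tibble(residue_name = "ARG", p = 0.5)), 1.0)
  c1 <- tibble::tibble(residue_name = c("ARG", "SER"), n = c(2L, 1L))
  c2 <- tibble::tibble(residue_name = c("SER", "LEU"), n = c(3L, 4L))
  csum <- dplyr::count(dplyr::bind_rows(
    tidyr::uncount(c1, n), tidyr::uncount(c2, n)), residue_name, name = "n")
  expect_equal(residue_propensity_score(csum, tbl),
               residue_propensity_score(c1, tbl) +
                 residue_propensity_score(c2, tbl))
  expect_error(residue_propensity_score(
    tibble::tibble(residue_name = "XXX", n = 1), tbl), "XXX")
})

test_that("a derived propensity table is finite, complete and signed sensibly", {
  cx <- toy_default()
  tbl <- compute_propensity_table(list(cx))
  expect_equal(nrow(tbl), 20)
  expect_true(all(is.finite(tbl$p)))
  # interface residues of the fixture get positive log-ratios
  im <- find_interface(cx$protein, cx$dna)
  int_types <- unique(im$residues$residue_name[im$residues$component ==
                                                 "protein"])
  expect_true(mean(tbl$p[tbl$residue_name %in% int_types] > 0) > 0.5)
})

test_that("Dp counts only listed donor atoms above the ASA threshold", {
  # exposed serine hydroxyls on an isolated peptide
  pep <- assign_radii(build_peptide(c("SER", "ALA", "SER", "THR")))
  d <- count_potential_donors(pep)
  expect_equal(d$dp, 3)  # OG, OG, OG1 all solvent exposed
  expect_setequal(d$donors$atom_name, c("OG", "OG1"))
  expect_true(all(d$donors$area >= 10))
  # an artificial map burying every donor drops Dp to zero
  asa0 <- compute_asa(pep)
  asa0$area <- 0
  expect_equal(count_potential_donors(pep, asa = asa0)$dp, 0)
})

test_that("Dp is monotone non-increasing in the ASA threshold", {
  pep <- assign_radii(build_peptide(rep(c("SER", "THR", "ALA"), 6)))
  asa <- compute_asa(pep)
  dps <- vapply(c(0, 5, 10, 20, 40, 80),
                function(m) count_potential_donors(pep, asa = asa,
                                                   min_asa = m)$dp,
                numeric(1))
  expect_true(all(diff(dps) <= 0))
  expect_equal(dps[1], 12)  # every listed donor atom present counts at 0
})

test_that("interface secondary structure classes follow the dihedral fractions", {
  helix <- assign_radii(build_peptide(rep("ALA", 12)))
  strand <- assign_radii(build_peptide(rep("ALA", 12), phi = -120, psi = 130))
  im_h <- fake_interface(cbind(1:12, 0, 0))
  expect_equal(classify_secondary_structure(helix, im_h)$class, "alpha")
  expect_equal(classify_secondary_structure(strand, im_h)$class, "beta")
  # half helix, half strand -> alphabeta
  mixed <- assign_radii(build_peptide(rep("ALA", 12),
                                      phi = c(rep(-57, 6), rep(-120, 6)),
                                      psi = c(rep(-47, 6), rep(130, 6))))
  cls <- classify_secondary_structure(mixed, im_h)
  expect_equal(cls$class, "alphabeta")
  expect_gte(cls$f_helix, 0.10)
  expect_gte(cls$f_strand, 0.10)
})

test_that("feature vectors assemble Rp, Dp and Ncons for an interface", {
  cx <- toy_default()
  im <- find_interface(cx$protein, cx$dna)
  seqs <- structure_residues(cx$protein)$residue_name
  aln <- make_synthetic_msa(paste(aa_one_letter(seqs),
                                  collapse = ""),
                            n_seqs = 20, rates = 0.3, seed = 5)
  fv <- interface_features(cx$protein, im, aln = aln)
  expect_true(is.finite(fv$rp))
  expect_gte(fv$dp, 0)
  expect_lte(fv$ncons, fv$n_interface_residues)
  fv2 <- interface_features(cx$protein, im)
  expect_true(is.na(fv2$ncons))
})
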