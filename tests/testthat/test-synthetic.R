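test_that("generators are deterministic: same seed, identical output", {
  c1 <- make_toy_complex(seed = 6)
  c2 <- make_toy_complex(seed = 6)
  expect_identical(c1$structure, c2$structure)
  a1 <- make_synthetic_msa("ASLTGN", n_seqs = 10, rates = 0.4, seed = 6)
  a2 <- make_synthetic_msa("ASLTGN", n_seqs = 10, rates = 0.4, seed = 6)
  expect_identical(a1$mat, a2$mat)
  # a peptide long enough to leave room for zero-overlap placements
  cl <- make_toy_complex(sequence = rep(c("SER", "ALA", "LEU", "THR"), 12),
                         n_bp = 6, dna_offset = -20, axis_separation = 15,
                         n_bridging_waters = 0, n_far_waters = 0, seed = 6)
  d1 <- make_decoy_set(cl, n_decoys = 3, overlap = 0, seed = 6)
  d2 <- make_decoy_set(cl, n_decoys = 3, overlap = 0, seed = 6)
  expect_identical(lapply(d1, function(s) s$x), lapply(d2, function(s) s$x))
})

test_that("the generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_toy_complex(seed = 9))
  invisible(make_synthetic_msa("ASLT", n_seqs = 5, rates = 0.5, seed = 9))
  expect_equal(runif(1), before)
})

test_that("a distant peptide yields an empty-interface ground truth", {
  cx <- make_toy_complex(axis_separation = 50, n_bridging_waters = 0,
                         n_far_waters = 0, seed = 2)
  expect_warning(im <- find_interface(cx$protein, cx$dna), "no interface")
  expect_equal(nrow(im$atoms), 0)
})

test_that("the idealised duplex respects fibre geometry and moieties", {
  dna <- build_bdna(rep(c("DA", "DT"), 5))
  expect_setequal(unique(dna$chain), c("B", "C"))
  p1 <- dplyr::filter(dna, chain == "B", atom_name == "P")
  expect_equal(diff(p1$x), rep(3.38, 9), tolerance = 1e-9)
  expect_setequal(unique(dna$moiety), c("phosphate", "sugar", "base"))
  # strand 2 is the reversed complement
  s1 <- dplyr::distinct(dplyr::filter(dna, chain == "B"),
                        residue_number, residue_name)
  s2 <- dplyr::distinct(dplyr::filter(dna, chain == "C"),
                        residue_number, residue_name)
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  expect_equal(unname(comp[s1$residue_name]),
               s2$residue_name[match(11 - s1$residue_number,
                                     s2$residue_number)])
})

test_that("planted interface structure is recovered by the pipeline", {
  cx <- make_toy_complex(n_bridging_waters = 1, n_far_waters = 1, seed = 3)
  hb <- detect_hbonds(cx$structure)
  wc <- classify_interface_waters(cx$structure, hb)
  got <- wc$waters$residue_number[wc$waters$category == "bridging"]
  expect_setequal(got, cx$truth$bridging_waters)
  im <- find_interface(cx$protein, cx$dna)
  expect_gt(nrow(im$atoms), 0)
})

test_that("substitution rates plant the entropy gradient", {
  aln0 <- make_synthetic_msa("ASLTGNAS", n_seqs = 40, rates = 0,
                             seed = 4)
  expect_true(all(vapply(1:8, function(j) column_entropy(aln0, j),
                         numeric(1)) == 0))
  aln <- make_synthetic_msa("AS", n_seqs = 200, rates = c(0, 1), seed = 4)
  expect_equal(column_entropy(aln, 1), 0)
  expect_gt(column_entropy(aln, 2), 2)  # approaches ln(20) ~ 3.0
})

test_that("decoy overlap schedules are honoured", {
  cx <- make_toy_complex(sequence = rep(c("SER", "ALA", "LEU", "THR"), 12),
                         n_bp = 6, dna_offset = -20, axis_separation = 15,
                         n_bridging_waters = 0, n_far_waters = 0, seed = 5)
  im <- find_interface(cx$protein, cx$dna)
  ds0 <- make_decoy_set(cx, n_decoys = 3, overlap = 0, seed = 5)
  for (d in ds0) {
    comps <- split_components(d, "A", c("B", "C"))
    imd <- suppressWarnings(find_interface(comps$protein, comps$dna))
    expect_equal(interface_overlap(im, imd), 0)
  }
  ds5 <- make_decoy_set(cx, n_decoys = 1, overlap = 0.5, seed = 5)
  comps <- split_components(ds5[[1]], "A", c("B", "C"))
  imd <- find_interface(comps$protein, comps$dna)
  expect_lt(abs(interface_overlap(im, imd) - 0.5), 0.1 + 1e-9)
})

test_that("infeasible overlap requests error", {
  # a short peptide leaves no room for a zero-overlap placement
  cx <- make_toy_complex(sequence = rep("ALA", 10), n_bp = 8,
                         n_bridging_waters = 0, n_far_waters = 0, seed = 7)
  expect_error(make_decoy_set(cx, n_decoys = 1, overlap = 0, seed = 7),
               "infeasible")
})
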