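test_that("a minimal PDB record parses into one protein atom", {
  st <- parse_structure(c("HEADER    test",
                          pdb_min_line(),
                          "END"))
  expect_equal(nrow(st), 1)
  expect_equal(st$component, "protein")
  expect_equal(st$atom_name, "CA")
  expect_equal(unique(st$chain), "A")
})

test_that("waters are tagged by residue name regardless of record type", {
  st <- parse_structure(c(
    pdb_min_line(),
    pdb_min_line(atom = "O", res = "HOH", chain = "W", resno = 2, x = 30,
                 rec = "HETATM", element = " O")))
  expect_equal(st$component, c("protein", "water"))
})

test_that("parse errors are informative", {
  expect_error(parse_structure("HEADER only"), "empty structure")
  bad <- c(pdb_min_line(), "ATOM      2  CB  ALA A   1      bad coords")
  expect_error(parse_structure(bad), "line 2")
})

test_that("highest-occupancy altloc wins, ties broken by letter", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       0.000   1.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       0.000   2.000   0.000  0.50  0.00           C")
  st <- parse_structure(lines)
  expect_equal(nrow(st), 2)
  expect_equal(st$x[st$atom_name == "CA"], 1.0)  # B has higher occupancy
  expect_equal(st$y[st$atom_name == "CB"], 1.0)  # tie -> altloc A
})

test_that("polarity is a total function of element; hydrogens are flagged", {
  st <- parse_structure(c(
    pdb_min_line(atom = "CA", element = " C"),
    pdb_min_line(atom = "N", element = " N"),
    pdb_min_line(atom = "SD", res = "MET", element = " S"),
    pdb_min_line(atom = "HA", element = " H")))
  expect_equal(st$polarity[st$element == "C"], "nonpolar")
  expect_equal(st$polarity[st$element == "N"], "polar")
  expect_equal(st$polarity[st$element == "S"], "nonpolar")
  expect_true(st$is_hydrogen[st$element == "H"])
  expect_false(any(st$is_hydrogen[st$element != "H"]))
})

test_that("only the first model of a multi-model file is read", {
  lines <- c("MODEL        1", pdb_min_line(), "ENDMDL",
             "MODEL        2", pdb_min_line(x = 5), "ENDMDL")
  st <- parse_structure(lines)
  expect_equal(nrow(st), 1)
  expect_equal(st$x, 0)
})

test_that("radii follow the bundled set with element fallback", {
  st <- make_atoms(tibble::tibble(
    atom_name = c("N", "O", "CA", "C", "SD", "P"),
    residue_name = c("ALA", "ALA", "ALA", "ALA", "MET", "DA"),
    chain = "A", residue_number = c(1, 1, 1, 1, 2, 3),
    x = seq(0, 50, length.out = 6), y = 0, z = 0))
  expect_equal(st$vdw_radius[st$atom_name == "N"], 1.65)
  expect_equal(st$vdw_radius[st$atom_name == "O"], 1.40)
  expect_equal(st$vdw_radius[st$atom_name == "CA"], 1.87)  # sp3 carbon
  expect_equal(st$vdw_radius[st$atom_name == "C"], 1.76)   # carbonyl
  expect_equal(st$vdw_radius[st$atom_name == "SD"], 1.85)
  expect_equal(st$vdw_radius[st$atom_name == "P"], 1.90)

  odd <- tibble::tibble(atom_name = "XX1", residue_name = "LIG", chain = "A",
                        residue_number = 1, x = 0, y = 0, z = 0)
  expect_warning(st2 <- make_atoms(odd), "fallback")
  expect_true(st2$vdw_radius > 0)
})

test_that("split_components partitions atoms and validates chains", {
  cx <- toy_default()
  parts <- split_components(cx$structure, "A", c("B", "C"))
  expect_equal(sort(unique(parts$protein$chain)), "A")
  expect_equal(sort(unique(parts$dna$chain)), c("B", "C"))
  expect_equal(nrow(parts$waters), sum(cx$structure$component == "water"))
  expect_equal(nrow(parts$protein) + nrow(parts$dna) + nrow(parts$waters),
               nrow(cx$structure))
  expect_error(split_components(cx$structure, "A", "A"), "overlap")
  expect_error(split_components(cx$structure, "Z", "B"), "available")
  expect_error(split_components(cx$structure, "B", "C"), "no amino acids")
})

test_that("PDB writing round-trips atom identity and coordinates", {
  cx <- toy_default()
  st2 <- parse_structure(write_pdb(cx$structure))
  expect_equal(nrow(st2), nrow(cx$structure))
  expect_equal(st2$atom_name, cx$structure$atom_name)
  expect_equal(st2$residue_name, cx$structure$residue_name)
  expect_lt(max(abs(st2$x - cx$structure$x),
                abs(st2$y - cx$structure$y),
                abs(st2$z - cx$structure$z)), 1e-3)
})
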