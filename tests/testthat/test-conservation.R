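fasta <- function(ids, seqs) {
  paste(paste0(">", ids, "\n", seqs), collapse = "\n")
}

test_that("aligned FASTA parses; ragged or single-sequence input errors", {
  aln <- read_msa(fasta(c("q", "h1", "h2"), c("ACDE", "ACDE", "ACDE")))
  expect_s3_class(aln, "pdi_alignment")
  expect_equal(unname(msa_identity(aln)), c(1, 1, 1))
  expect_error(read_msa(fasta(c("q", "h1"), c("ACDE", "ACD"))), "ragged")
  expect_error(read_msa(fasta("q", "ACDE")), "at least 2")
})

test_that("identity is computed over mutually non-gap columns", {
  aln <- read_msa(fasta(c("q", "h1"), c("AC-D", "ACED")))
  expect_equal(unname(msa_identity(aln))[2], 1)  # 3 comparable columns, all equal
  aln2 <- read_msa(fasta(c("q", "h1"), c("ACKD", "ACE-")))
  expect_equal(unname(msa_identity(aln2))[2], 2 / 3)
})

test_that("homolog filtering keeps the query and respects the cutoff", {
  seqs <- c("AAAAAAAAAA",
            "AAAAAAAAAC",  # 0.9
            "AAAAACCCCC",  # 0.5
            "AACCCCCCCC")  # 0.2
  aln <- read_msa(fasta(c("q", "a", "b", "c"), seqs))
  kept <- filter_homologs(aln, 0.30)
  expect_equal(kept$ids, c("q", "a", "b"))
  expect_equal(length(filter_homologs(aln, 0)$ids), 4)
  # raising the cutoff never increases the retained count
  ns <- vapply(c(0, 0.3, 0.6, 0.9),
               function(ct) length(filter_homologs(aln, ct)$ids), numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(filter_homologs(aln, 0.99), "fewer than 2")
})

test_that("column entropies match hand values and a counting oracle", {
  aln <- read_msa(fasta(paste0("s", 1:4), c("RRKA", "RRKC", "RKRD", "RKRE")))
  expect_equal(column_entropy(aln, 1), 0)
  expect_equal(column_entropy(aln, 2), log(2))
  expect_equal(column_entropy(aln, 4), log(4))
  # independent recount oracle on a random alignment
  aln2 <- make_synthetic_msa("ACDEFGHIKLMNPQRSTVWY", n_seqs = 30,
                             rates = 0.5, seed = 3)
  for (j in c(1, 7, 20)) {
    col <- aln2$mat[, j]
    f <- table(col) / length(col)
    expect_equal(column_entropy(aln2, j), -sum(f * log(f)))
  }
  expect_error(column_entropy(aln, 9), "out of range")
})

test_that("all-gap columns are flagged undefined", {
  aln <- read_msa(fasta(c("q", "h"), c("A-C", "A-C")))
  expect_warning(s <- column_entropy(aln, 2), "all-gap")
  expect_true(is.na(s))
})

test_that("the entropy profile applies the strict Ncons inequality", {
  # alignment whose columns have entropies {0, ln2, ln2, ln4}
  aln <- read_msa(fasta(paste0("s", 1:4), c("RRKA", "RRKC", "RKRD", "RKRE")))
  pep <- assign_radii(build_peptide(c("ARG", "ARG", "LYS", "ALA")))
  im <- fake_interface(cbind(1:4, 0, 0))
  prof <- interface_entropy_profile(aln, im, pep, chain = "A")
  expect_equal(attr(prof, "n"), 4)
  expect_equal(prof$s, c(0, log(2), log(2), log(4)))
  expect_equal(attr(prof, "mean_interface"), mean(prof$s))
  expect_equal(attr(prof, "n_cons"), sum(prof$s < mean(prof$s)))
  # all-equal entropies give Ncons = 0 under the strict inequality
  aln_eq <- read_msa(fasta(paste0("s", 1:3), c("RRKA", "RRKA", "RRKA")))
  prof_eq <- interface_entropy_profile(aln_eq, im, pep, chain = "A")
  expect_equal(attr(prof_eq, "n_cons"), 0)
})

test_that("row order does not change entropies; duplicates re-weight them", {
  aln <- make_synthetic_msa("ASLTGNASLTGN", n_seqs = 12, rates = 0.4,
                            seed = 9)
  perm <- dnaface:::new_alignment(
    aln$ids[c(1, sample(2:12))],
    apply(aln$mat[c(1, sample(2:12)), ], 1, paste, collapse = ""))
  for (j in c(1, 5, 12)) {
    expect_equal(column_entropy(aln, j), column_entropy(perm, j))
  }
  # duplicating one homolog changes each column by the frequency-reweighting
  # oracle amount
  dup <- dnaface:::new_alignment(c(aln$ids, "dup"),
                                 apply(aln$mat[c(1:12, 2), ], 1, paste,
                                       collapse = ""))
  for (j in c(2, 8)) {
    counts <- table(c(aln$mat[, j], aln$mat[2, j]))
    f <- counts / sum(counts)
    expect_equal(column_entropy(dup, j), -sum(f * log(f)))
  }
})

test_that("core columns planted conserved come out below rim columns", {
  rec <- conservation_recovery(n_reps = 5, seed = 2)
  expect_true(all(rec$core_lt_rim))
  expect_true(all(rec$ncons_exact))
})
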