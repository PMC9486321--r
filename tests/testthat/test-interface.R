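test_that("components far apart yield an empty interface with a warning", {
  cx <- toy_default()
  far_dna <- cx$dna
  far_dna$y <- far_dna$y + 50
  expect_warning(im <- find_interface(cx$protein, far_dna), "no interface")
  expect_equal(nrow(im$atoms), 0)
  stats <- interface_statistics(im)
  expect_equal(stats$total[stats$parameter == "interface_area"], 0)
  expect_equal(stats$total[stats$parameter == "n_atoms"], 0)
})

test_that("interface atoms equal a brute-force per-atom delta-ASA check", {
  cx <- toy_default()
  im <- find_interface(cx$protein, cx$dna)
  # brute force: full unmasked recomputation, manual comparison
  ap <- compute_asa(cx$protein)
  ad <- compute_asa(cx$dna)
  ac <- compute_asa(dnaface:::new_structure(dplyr::bind_rows(cx$protein,
                                                             cx$dna)))
  free <- c(ap$area, ad$area)
  flagged <- which(pmax(free - ac$area, 0) > 0.1)
  got <- dplyr::inner_join(im$atoms, dplyr::mutate(ac, i = dplyr::row_number()),
                           by = c("chain", "residue_number", "insert",
                                  "residue_name", "atom_name"))
  expect_setequal(got$i, flagged)
})

test_that("raising the ASA threshold never adds interface atoms", {
  cx <- toy_default()
  counts <- vapply(c(0.1, 0.5, 1, 2, 5), function(th) {
    nrow(suppressWarnings(find_interface(cx$protein, cx$dna,
                                         asa_threshold = th))$atoms)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("core requires a fully buried atom; rim is the remainder", {
  cx <- toy_default()
  im <- find_interface(cx$protein, cx$dna)
  expect_true(all(im$residues$region %in% c("core", "rim")))
  by_res <- im$atoms |>
    dplyr::group_by(chain, residue_number, insert) |>
    dplyr::summarise(any_buried = any(area_complexed <= 0.1),
                     .groups = "drop")
  joined <- dplyr::left_join(im$residues, by_res,
                             by = c("chain", "residue_number", "insert"))
  expect_equal(joined$region == "core", joined$any_buried)

  # overriding the complex map re-labels regions
  fake_asa <- im$asa$complex
  fake_asa$area <- 5  # nothing buried
  im2 <- dissect_core_rim(im, fake_asa)
  expect_true(all(im2$residues$region == "rim"))
})

test_that("statistics sum by construction and fractions are sane", {
  cx <- toy_default()
  im <- find_interface(cx$protein, cx$dna)
  s <- interface_statistics(im)
  get <- function(p, col) s[[col]][s$parameter == p]
  expect_equal(get("interface_area", "total"),
               get("interface_area", "protein") + get("interface_area", "dna"))
  expect_equal(get("n_atoms", "total"), nrow(im$atoms))
  expect_equal(get("n_residues", "total"), nrow(im$residues))
  expect_true(get("fraction_nonpolar", "total") >= 0 &&
                get("fraction_nonpolar", "total") <= 1)
  expect_true(get("fraction_fully_buried", "total") >= 0 &&
                get("fraction_fully_buried", "total") <= 1)
  expect_lte(get("nonpolar_area", "total"), get("interface_area", "total"))
})

test_that("a symmetric homodimer has equal per-chain interface areas", {
  cx <- toy_default()
  # build an exactly 2-fold-symmetric complex: the second protein chain and
  # the second strand are both the C2 image (about the duplex axis) of the
  # first, so the two chains see identical environments
  sep <- 13.5
  c2 <- function(st, new_chain) {
    st$chain <- new_chain
    st$y <- 2 * sep - st$y
    st$z <- -st$z
    st
  }
  mate <- c2(cx$protein, "D")
  strand_b <- dplyr::filter(cx$dna, chain == "B")
  dna_sym <- dnaface:::new_structure(dplyr::bind_rows(strand_b,
                                                      c2(strand_b, "C")))
  both <- dnaface:::new_structure(dplyr::bind_rows(cx$protein, mate))
  im <- find_interface(both, dna_sym)
  per_chain <- im$atoms |>
    dplyr::filter(component == "protein") |>
    dplyr::group_by(chain) |>
    dplyr::summarise(area = sum(delta_area))
  expect_equal(nrow(per_chain), 2)
  expect_lt(abs(diff(per_chain$area)) / mean(per_chain$area), 0.02)
})

test_that("interface residues are invariant to atom order in the input", {
  cx <- toy_default()
  im1 <- find_interface(cx$protein, cx$dna)
  set.seed(3)
  shuf <- cx$protein[sample(nrow(cx$protein)), ]
  im2 <- find_interface(dnaface:::new_structure(shuf), cx$dna)
  key <- function(im) sort(paste(im$residues$chain, im$residues$residue_number))
  expect_equal(key(im1), key(im2))
})

test_that("patch clustering matches a union-find oracle", {
  # two residues 25 A apart at cutoff 20 -> 2 patches
  im <- fake_interface(cbind(c(0, 25), 0, 0))
  expect_equal(max(cluster_patches(im, 20)$residues$patch), 2)
  # chain with 15 A steps -> single-linkage transitivity gives 1 patch
  im <- fake_interface(cbind(seq(0, 75, by = 15), 0, 0))
  expect_equal(max(cluster_patches(im, 20)$residues$patch), 1)
  # 30 random residues vs brute-force union-find
  set.seed(11)
  xyz <- cbind(runif(30, 0, 60), runif(30, 0, 60), runif(30, 0, 60))
  got <- cluster_patches(fake_interface(xyz), 20)$residues$patch
  want <- union_find_clusters(xyz, 20)
  # same partition up to labelling
  expect_equal(length(unique(got)), length(unique(want)))
  expect_true(all(tapply(want, got, function(v) length(unique(v))) == 1))
})

test_that("projection drops the smallest-variance axis and preserves rigid motion", {
  set.seed(5)
  # oblate cloud: z variance smallest
  xyz <- cbind(rnorm(40, sd = 8), rnorm(40, sd = 4), rnorm(40, sd = 0.5))
  im <- fake_interface(xyz)
  pr <- project_interface(im)
  ev <- eigen(cov(scale(xyz, scale = FALSE)), symmetric = TRUE)$values
  expect_equal(min(attr(pr, "eigenvalues")), min(ev), tolerance = 1e-8)

  # points already in a plane: projection preserves all pairwise distances
  planar <- cbind(runif(12, 0, 10), runif(12, 0, 10), 0)
  prp <- project_interface(fake_interface(planar))
  expect_equal(as.numeric(dist(cbind(prp$px, prp$py))),
               as.numeric(dist(planar)), tolerance = 1e-8)

  # rigid rotation leaves projected inter-point distances unchanged
  th <- 0.9
  rotm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pr2 <- project_interface(fake_interface(xyz %*% t(rotm)))
  expect_equal(as.numeric(dist(cbind(pr2$px, pr2$py))),
               as.numeric(dist(cbind(pr$px, pr$py))), tolerance = 1e-6)

  # collinear geometry is degenerate
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(project_interface(fake_interface(line)), "collinear")
})
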