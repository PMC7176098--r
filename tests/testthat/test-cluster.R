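cfg <- test_config()

test_that("bit-score distance is 0 for identical, near 1 for unrelated", {
  set.seed(3)
  s <- random_protein_seq(200)
  u <- random_protein_seq(200)
  p <- protein_set(c("A", "B", "C"), c(s, s, u))
  dm <- bitscore_distance(p, cfg)
  expect_equal(dm$d["A", "B"], 0)
  expect_gt(dm$d["A", "C"], 0.8)
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(dm$d >= 0 & dm$d <= 1))
})

test_that("the distance transform matches direct arithmetic on a toy set", {
  set.seed(7)
  s1 <- random_protein_seq(150)
  s2 <- tmskit:::with_seed(4, tmskit:::mutate_sequence(s1, 0.3))
  s3 <- random_protein_seq(150)
  p <- protein_set(c("P1", "P2", "P3"), c(s1, s2, s3))
  dm <- bitscore_distance(p, cfg)
  consts <- matrix_constants(cfg$matrix, cfg$gap_open, cfg$gap_extend)
  b <- function(a, bb) bit_score(
    smith_waterman(a, bb, cfg)$raw_score, consts)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- pair[1]; j <- pair[2]
    expected <- min(max(
      1 - b(p$sequence[i], p$sequence[j]) /
        min(b(p$sequence[i], p$sequence[i]),
            b(p$sequence[j], p$sequence[j])), 0), 1)
    expect_equal(dm$d[i, j], expected, tolerance = 1e-10)
  }
})

test_that("max-self normalization gives distances at least as large", {
  set.seed(13)
  p <- protein_set(c("A", "B"),
                   c(random_protein_seq(120),
                     paste0(random_protein_seq(60),
                            random_protein_seq(120))))
  d_min <- bitscore_distance(p, cfg, normalize = "min_self")$d["A", "B"]
  d_max <- bitscore_distance(p, cfg, normalize = "max_self")$d["A", "B"]
  expect_gte(d_max, d_min)
})

test_that("agglomerative coefficient worked examples hold exactly", {
  # two items: each first merges at the final height, AC = 0
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  t2 <- agnes_average(d2)
  expect_equal(t2$agglomerative_coefficient, 0)
  # three points, d(1,2)=0.1, others 1.0: merges at 0.1 then 1.0,
  # AC = (0.9 + 0.9 + 0)/3 = 0.6
  d3 <- matrix(c(0, .1, 1, .1, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- agnes_average(d3)
  expect_equal(t3$agglomerative_coefficient, 0.6)
  expect_equal(sort(t3$merges$height), c(0.1, 1.0))
  # all-equal distances: AC = 0
  d4 <- matrix(0.5, 4, 4); diag(d4) <- 0
  dimnames(d4) <- list(letters[1:4], letters[1:4])
  expect_equal(agnes_average(d4)$agglomerative_coefficient, 0)
  expect_error(agnes_average(matrix(0, 1, 1)), "at least 2")
})

test_that("tight families far apart give AC near 1 and are recovered", {
  fams <- lapply(1:3, function(f) {
    anc <- make_protein("4+4", seed = 400 + f, accession = paste0("F", f))
    evolve_family(anc, family_spec(n_members = 4L, p_mut = 0.05,
                                   seed = 410 + f),
                  prefix = paste0("F", f, "_"), family = paste0("Fam", f))
  })
  prot <- do.call(rbind, lapply(fams, `[[`, "proteins"))
  class(prot) <- c("protein_set", "data.frame")
  dm <- bitscore_distance(prot, cfg)
  tree <- agnes_average(dm)
  expect_gt(tree$agglomerative_coefficient, 0.8)
  cl <- cut_clusters(tree, 3)
  expect_equal(mclust::adjustedRandIndex(cl[prot$accession], prot$family), 1)
})

test_that("clustering is invariant to input order", {
  set.seed(19)
  seqs <- vapply(1:6, function(i) random_protein_seq(150), "")
  seqs[2] <- tmskit:::with_seed(2, tmskit:::mutate_sequence(seqs[1], 0.2))
  seqs[4] <- tmskit:::with_seed(3, tmskit:::mutate_sequence(seqs[3], 0.2))
  p <- protein_set(paste0("S", 1:6), seqs)
  perm <- c(4, 1, 6, 2, 3, 5)
  p2 <- p[perm, ]; class(p2) <- c("protein_set", "data.frame")
  t1 <- agnes_average(bitscore_distance(p, cfg))
  t2 <- agnes_average(bitscore_distance(p2, cfg))
  expect_equal(sort(t1$merges$height), sort(t2$merges$height),
               tolerance = 1e-10)
})

test_that("tree export round-trips topology and heights", {
  d3 <- matrix(c(0, .1, 1, .1, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("x", "y", "z label"), c("x", "y", "z label")))
  tree <- agnes_average(d3)
  nwk <- tempfile(fileext = ".nwk")
  export_tree(tree, nwk, "newick")
  phy <- ape::read.tree(nwk)
  expect_equal(sort(phy$tip.label), sort(c("x", "y", "z_label")))
  nex <- tempfile(fileext = ".nex")
  export_tree(tree, nex, "nexus")
  phy2 <- ape::read.nexus(nex)
  expect_equal(ape::Ntip(phy2), 3)
  # cophenetic depth of the x-y pair reflects the 0.1 merge height
  coph <- ape::cophenetic.phylo(phy2)
  expect_lt(coph["x", "y"], coph["x", grep("z", rownames(coph), value = TRUE)])
})

test_that("representative picker respects per-family targets", {
  set.seed(23)
  seqs <- vapply(1:6, function(i) random_protein_seq(120), "")
  p <- protein_set(paste0("S", 1:6), seqs)
  dm <- bitscore_distance(p, cfg)
  fams <- setNames(rep(c("f1", "f2"), each = 3), p$accession)
  sel <- pick_representatives(dm, fams, n_per_family = 2L)
  expect_length(sel, 4L)
  expect_equal(as.integer(table(fams[sel])), c(2L, 2L))
})
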