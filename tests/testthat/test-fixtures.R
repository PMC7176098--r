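cfg <- test_config()

test_that("topology strings control the planted TMS count deterministically", {
  mp <- make_protein("3", seed = 9, accession = "P")
  expect_equal(nrow(mp$topology), 3L)
  mp2 <- make_protein("4+2+4", seed = 9, accession = "P")
  expect_equal(nrow(mp2$topology), 10L)
  expect_identical(make_protein("4+4", seed = 5)$proteins$sequence,
                   make_protein("4+4", seed = 5)$proteins$sequence)
  expect_error(make_protein("4++", seed = 1), "malformed")
  expect_error(make_protein("abc", seed = 1), "malformed")
})

test_that("planted intervals lie on hydrophobic segments within bounds", {
  kd <- tmskit:::.kd_scale
  for (s in 1:20) {
    topo_str <- sample(c("4", "4+4", "3+4", "4+2+4"), 1)
    mp <- make_protein(topo_str, seed = 500 + s, accession = "P")
    iv <- tms_of(mp$topology, "P")
    L <- nchar(mp$proteins$sequence[1])
    expect_true(all(iv[, "start"] >= 1 & iv[, "end"] <= L))
    for (i in seq_len(nrow(iv))) {
      seg <- strsplit(substr(mp$proteins$sequence[1], iv[i, "start"],
                             iv[i, "end"]), "")[[1]]
      expect_gt(mean(kd[seg]), 0)  # hydrophobic majority
    }
  }
})

test_that("zero mutation reproduces the post-event ancestor exactly", {
  anc <- make_protein("4", seed = 31, accession = "A")
  fam <- evolve_family(anc, family_spec(events = list("duplicate"),
                                        n_members = 2L, p_mut = 0,
                                        p_indel = 0, seed = 77))
  expect_equal(nchar(fam$proteins$sequence[1]),
               2L * nchar(anc$proteins$sequence[1]))
  expect_identical(fam$proteins$sequence[1], fam$proteins$sequence[2])
  # exact internal repeat by construction
  half <- nchar(anc$proteins$sequence[1])
  expect_identical(substr(fam$proteins$sequence[1], 1, half),
                   substr(fam$proteins$sequence[1], half + 1L, 2L * half))
  expect_equal(nrow(fam$topology[fam$topology$protein == "M1", ]), 8L)
})

test_that("evolution events update planted topology consistently", {
  anc <- make_protein("4", seed = 41, accession = "A")
  dup <- tmskit:::apply_event(anc, "duplicate")
  expect_equal(nrow(dup$topology), 8L)
  lost <- tmskit:::apply_event(dup, "lose_n_terminal_tms")
  expect_equal(nrow(lost$topology), 7L)
  ins <- tmskit:::apply_event(dup, list("insert_central_tms", 2L))
  expect_equal(nrow(ins$topology), 10L)
  # all events keep hydrophobic-majority slices
  kd <- tmskit:::.kd_scale
  for (m in list(dup, lost, ins)) {
    iv <- tms_of(m$topology, m$proteins$accession[1])
    for (i in seq_len(nrow(iv))) {
      seg <- strsplit(substr(m$proteins$sequence[1], iv[i, "start"],
                             iv[i, "end"]), "")[[1]]
      expect_gt(mean(kd[seg]), 0)
    }
  }
})

test_that("indels stay in loops: planted TMS slices survive divergence", {
  kd <- tmskit:::.kd_scale
  anc <- make_protein("4+4", seed = 51, accession = "A")
  fam <- evolve_family(anc, family_spec(n_members = 5L, p_mut = 0.3,
                                        p_indel = 0.3, seed = 52),
                       prefix = "M")
  for (acc in fam$proteins$accession) {
    iv <- tms_of(fam$topology, acc)
    expect_equal(nrow(iv), 8L)
    seqc <- seq_of(fam$proteins, acc)
    expect_true(all(iv[, "end"] <= nchar(seqc)))
    for (i in seq_len(nrow(iv))) {
      seg <- strsplit(substr(seqc, iv[i, "start"], iv[i, "end"]), "")[[1]]
      expect_gt(mean(kd[seg]), 0)
    }
  }
})

test_that("pairwise identity decreases with the mutation probability", {
  med_id <- vapply(c(0.05, 0.2, 0.4), function(p) {
    ids <- vapply(1:6, function(s) {
      anc <- make_protein("4+4", seed = 600 + s, accession = "A")
      fam <- evolve_family(anc, family_spec(n_members = 2L, p_mut = p,
                                            seed = 610 + s))
      smith_waterman(fam$proteins$sequence[1], fam$proteins$sequence[2],
                     cfg)$identity
    }, numeric(1))
    median(ids)
  }, numeric(1))
  expect_true(all(diff(med_id) < 0))
})

test_that("benchmark datasets are reproducible and correctly labeled", {
  bm1 <- make_benchmark(seed = 71)
  bm2 <- make_benchmark(seed = 71)
  expect_identical(bm1$proteins$sequence, bm2$proteins$sequence)
  expect_setequal(unique(bm1$truth$family),
                  c("FamA", "FamD", "Decoy1", "Decoy2"))
  expect_true(all(bm1$truth$related == grepl("^Fam", bm1$truth$family)))
  # planted topologies exist for the related families only
  expect_setequal(unique(bm1$topology$protein),
                  bm1$truth$accession[bm1$truth$related])
})

test_that("decoy families are composition-matched to the real founders", {
  bm <- make_benchmark(seed = 73)
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  freq <- function(seqs) {
    ch <- strsplit(paste(seqs, collapse = ""), "")[[1]]
    vapply(aa20, function(a) mean(ch == a), numeric(1))
  }
  real <- freq(bm$proteins$sequence[bm$truth$related])
  fake <- freq(bm$proteins$sequence[!bm$truth$related])
  # founders are exact permutations; member divergence drifts composition
  # only slightly
  expect_lt(max(abs(real - fake)), 0.02)
})
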