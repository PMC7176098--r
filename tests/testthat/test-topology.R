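cfg <- test_config()

test_that("hydropathy profile of homopolymers is the scale constant", {
  polyI <- list(accession = "PI", sequence = strrep("I", 40))
  hp <- hydropathy_profile(polyI, window = 19)
  expect_true(all(abs(hp$values - 4.5) < 1e-12))
  expect_true(all(hp$edge[1:9]) && !hp$edge[10])
  polyR <- list(accession = "PR", sequence = strrep("R", 40))
  expect_true(all(abs(hydropathy_profile(polyR, window = 19)$values + 4.5)
                  < 1e-12))
})

test_that("window means match direct arithmetic on an alternating sequence", {
  rec <- list(accession = "ALT", sequence = strrep("IR", 10))
  hp <- hydropathy_profile(rec, window = 3)
  kd <- c(I = 4.5, R = -4.5)
  chars <- strsplit(rec$sequence, "")[[1]]
  for (i in 2:19)
    expect_equal(hp$values[i], mean(kd[chars[(i - 1):(i + 1)]]))
  # shrunk ends
  expect_equal(hp$values[1], mean(kd[chars[1:2]]))
})

test_that("planted TMSs are recovered at default thresholds across seeds", {
  rec <- vapply(1:100, function(s) {
    mp <- make_protein("4+4", seed = s, accession = "P")
    pred <- predict_tms(hydropathy_profile(mp$proteins[1, ], window = 19), cfg)
    tms_recovery(mp$topology, pred, "P")
  }, numeric(1))
  expect_gte(mean(rec), 0.95)
})

test_that("hydrophilic sequences produce no TMS calls", {
  rec <- list(accession = "HYD", sequence = strrep("RKDE", 30))
  pred <- predict_tms(hydropathy_profile(rec, window = 19), cfg)
  expect_equal(nrow(pred), 0L)
})

test_that("runs separated by less than the merge gap are merged", {
  # synthetic profile: two plateaus above threshold split by a 3-residue dip
  prof <- structure(list(protein = "SYN",
                         values = c(rep(0, 5), rep(2, 18), rep(0.5, 3),
                                    rep(2, 18), rep(0, 5)),
                         edge = rep(FALSE, 49), scale = "kyte-doolittle",
                         window = 19L),
                    class = "hydropathy_profile")
  pred <- predict_tms(prof, cfg)  # merge gap 4 > 3
  expect_equal(nrow(pred), 2L)  # merged run of 39 > max_len 30 then split
  expect_equal(pred$start[1], 6L)
  expect_equal(pred$end[2], 44L)
  # with a wide dip the runs stay separate
  prof$values <- c(rep(0, 5), rep(2, 18), rep(0.5, 6), rep(2, 18), rep(0, 5))
  prof$edge <- rep(FALSE, length(prof$values))
  pred2 <- predict_tms(prof, cfg)
  expect_equal(nrow(pred2), 2L)
  expect_equal(pred2$end[1] - pred2$start[1] + 1L, 18L)
})

test_that("MSA profile of identical rows equals the single-sequence profile", {
  mp <- make_protein("3", seed = 2, accession = "P")
  s <- mp$proteins$sequence[1]
  msa <- tmskit:::as_msa(setNames(rep(s, 4), paste0("r", 1:4)))
  prof <- msa_profile(msa, window = 19, config = cfg)
  hp <- hydropathy_profile(mp$proteins[1, ], window = 19)
  expect_equal(prof$columns$avg_hydropathy, hp$values)
  expect_true(all(prof$columns$gap_fraction == 0))
})

test_that("MSA profile is invariant to row duplication and order", {
  rows <- setNames(c("MKIL-VA", "MR-LFVA", "MKILHVA"), paste0("s", 1:3))
  msa <- tmskit:::as_msa(rows)
  p1 <- msa_profile(msa, config = cfg)
  p2 <- msa_profile(tmskit:::as_msa(c(rows, rows)), config = cfg)
  p3 <- msa_profile(tmskit:::as_msa(rev(rows)), config = cfg)
  expect_equal(p1$columns$avg_hydropathy, p2$columns$avg_hydropathy)
  expect_equal(p1$columns$avg_similarity, p2$columns$avg_similarity)
  expect_equal(p1$columns, p3$columns)
})

test_that("gap columns average over non-gap residues only", {
  msa <- tmskit:::as_msa(setNames(c("MK-", "MKV"), c("a", "b")))
  prof <- msa_profile(msa, config = cfg)
  kd <- c(M = 1.9, K = -3.9, V = 4.2)
  expect_equal(prof$columns$avg_hydropathy[3], unname(kd["V"]))
  expect_equal(prof$columns$gap_fraction, c(0, 0, 0.5))
  expect_error(msa_profile(character(0)), "empty")
})

test_that("MSA trimming follows the strict gap-fraction rule and is idempotent", {
  # column 2 has 3/10 gaps (exactly 0.30): removed under "< 30%"
  rows <- c(paste0("A", "-", "C"), paste0("A", "-", "C"), paste0("A", "-", "C"),
            rep("AMC", 7))
  msa <- tmskit:::as_msa(setNames(rows, paste0("r", 1:10)))
  tr <- trim_msa(msa)
  expect_equal(unname(nchar(tr[1])), 2L)
  expect_equal(trim_msa(tr), tr)
  # gap-free MSA unchanged; all-gap column removed
  clean <- tmskit:::as_msa(setNames(c("MKV", "MRV"), c("a", "b")))
  expect_equal(trim_msa(clean), clean)
  gappy <- tmskit:::as_msa(setNames(c("M-V", "M-V"), c("a", "b")))
  expect_equal(unname(nchar(trim_msa(gappy)[1])), 2L)
})

test_that("TMS complexity classification spans simple, twilight, complex", {
  polyL <- list(accession = "L", sequence = strrep("L", 25))
  expect_equal(classify_tms(polyL, c(1, 25)), "simple")
  all20 <- list(accession = "X",
                sequence = "ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV")
  expect_equal(classify_tms(all20, c(1, 40)), "complex")
  # 4 equiprobable hydrophobic residues: entropy exactly 2 bits -> twilight
  mix4 <- list(accession = "T", sequence = strrep("ILVF", 6))
  expect_equal(classify_tms(mix4, c(1, 24)), "twilight")
  expect_error(classify_tms(polyL, c(10, 30)), "bounds")
})
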