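cfg <- test_config()

test_that("screening retains the query and its family, not random decoys", {
  anc <- make_protein("4+4", seed = 12, accession = "ANC")
  fam <- evolve_family(anc, family_spec(n_members = 3L, p_mut = 0.2,
                                        seed = 19), prefix = "F",
                       family = "Fam")
  set.seed(91)
  decoys <- protein_set(paste0("R", 1:3),
                        vapply(1:3, function(i)
                          random_protein_seq(nchar(fam$proteins$sequence[1])),
                          ""))
  db <- rbind(fam$proteins, decoys)
  class(db) <- c("protein_set", "data.frame")
  sl <- screen_homologs(fam$proteins[1, ], db, cfg)
  hits <- sl[["F1"]]$hits$accession
  expect_true("F1" %in% hits)  # self-hit passes both filters
  expect_setequal(hits, c("F1", "F2", "F3"))
  expect_true(all(sl[["F1"]]$evalue < cfg$screen_evalue))
  expect_error(screen_homologs(fam$proteins[1, ], db[0, ], cfg), "empty")
})

test_that("partial-coverage hits are excluded by the 40% rule", {
  set.seed(17)
  q <- random_protein_seq(150)
  partial <- paste0(substr(q, 1, 45), random_protein_seq(105))
  full <- q
  db <- protein_set(c("FULL", "PART"), c(full, partial))
  sl <- screen_homologs(protein_set("Q", q), db, cfg)
  expect_true("FULL" %in% sl$Q$hits$accession)
  a <- smith_waterman(q, partial, cfg)
  if (a$coverage_shorter < 0.40)  # guard: construction met its purpose
    expect_false("PART" %in% sl$Q$hits$accession)
})

test_that("TMS correspondence of a self-alignment is the identity pairing", {
  fam <- duplicated_fixture(seed = 41, acc = "S")
  rec <- fam$proteins[1, ]
  aln <- smith_waterman(rec$sequence, rec$sequence, cfg,
                        query = rec$accession, subject = rec$accession)
  corr <- map_tms_correspondence(aln, fam$topology, fam$topology)
  expect_equal(corr$n_aligned_tms, 8L)
  expect_equal(corr$pairs$tms_b, 1:8)
  expect_equal(corr$pairs$tms_c, 1:8)
})

test_that("loss of the N-terminal TMS shifts the correspondence by one", {
  parent <- duplicated_fixture(seed = 43, acc = "P")
  child <- tmskit:::apply_event(
    list(proteins = parent$proteins[1, ], topology = parent$topology),
    "lose_n_terminal_tms")
  aln <- smith_waterman(child$proteins$sequence[1],
                        parent$proteins$sequence[1], cfg,
                        query = child$proteins$accession[1],
                        subject = parent$proteins$accession[1])
  corr <- map_tms_correspondence(aln, child$topology, parent$topology)
  expect_equal(corr$n_aligned_tms, 7L)
  expect_equal(corr$pairs$tms_c, corr$pairs$tms_b + 1L)
})

test_that("correspondence is symmetric under swapping the alignment", {
  fam <- duplicated_fixture(seed = 47, acc = "W")
  rec <- fam$proteins[1, ]
  other <- tmskit:::with_seed(5, tmskit:::mutate_sequence(rec$sequence, 0.2))
  p2 <- protein_set("W2", other)
  topo2 <- tms_annotation(rep("W2", 8),
                          tms_of(fam$topology, rec$accession)[, "start"],
                          tms_of(fam$topology, rec$accession)[, "end"],
                          source = "planted")
  a12 <- smith_waterman(rec$sequence, other, cfg, query = rec$accession,
                        subject = "W2")
  a21 <- smith_waterman(other, rec$sequence, cfg, query = "W2",
                        subject = rec$accession)
  c12 <- map_tms_correspondence(a12, fam$topology, topo2)
  c21 <- map_tms_correspondence(a21, topo2, fam$topology)
  expect_equal(c12$pairs$tms_b, c21$pairs$tms_c)
  expect_equal(c12$pairs$tms_c, c21$pairs$tms_b)
})

test_that("a loop-confined alignment yields an empty correspondence", {
  fam <- duplicated_fixture(seed = 53, acc = "L")
  aln <- smith_waterman(fam$proteins$sequence[1], fam$proteins$sequence[1],
                        cfg, query = fam$proteins$accession[1],
                        subject = fam$proteins$accession[1])
  # restrict the alignment artificially to the N-terminal loop
  iv <- tms_of(fam$topology, fam$proteins$accession[1])
  loop_len <- iv[1, "start"] - 1L
  aln$q_aln <- aln$s_aln <- substr(fam$proteins$sequence[1], 1, loop_len)
  aln$q_start <- aln$s_start <- 1L
  aln$q_end <- aln$s_end <- loop_len
  corr <- map_tms_correspondence(aln, fam$topology, fam$topology)
  expect_equal(corr$n_aligned_tms, 0L)
})

test_that("domain overlap passes inside the alignment and fails outside", {
  fam <- duplicated_fixture(seed = 61, acc = "D")
  rec <- fam$proteins[1, ]
  other <- protein_set("D2", rec$sequence)
  topo2 <- tms_annotation(rep("D2", 8),
                          tms_of(fam$topology, rec$accession)[, "start"],
                          tms_of(fam$topology, rec$accession)[, "end"],
                          source = "planted")
  aln <- smith_waterman(rec$sequence, other$sequence[1], cfg,
                        query = rec$accession, subject = "D2")
  iv <- tms_of(fam$topology, rec$accession)
  hits_b <- domain_hits(rec$accession, "PFX1", iv[1, "start"], iv[4, "end"],
                        1e-20, clan = "CLX")
  hits_c <- domain_hits("D2", "PFX2", iv[1, "start"], iv[4, "end"], 1e-20,
                        clan = "CLX")
  res <- check_domain_overlap(aln, hits_b, hits_c, fam$topology, topo2)
  expect_true(res$pass)
  expect_true(res$clan_support)  # same clan, different accessions
  # a domain wholly outside the aligned span fails
  aln2 <- aln
  aln2$q_end <- iv[1, "start"] - 2L; aln2$q_start <- 1L
  out <- domain_hits(rec$accession, "PFX1", iv[2, "start"], iv[4, "end"],
                     1e-20)
  res2 <- check_domain_overlap(aln2, out, hits_c, fam$topology, topo2)
  expect_false(res2$pass)
  res3 <- check_domain_overlap(aln, hits_b[0, ], hits_c[0, ], fam$topology,
                               topo2)
  expect_false(res3$pass)
  expect_equal(res3$reason, "no domains")
})

test_that("domain projection transfers a mutated region, not random ones", {
  fam <- duplicated_fixture(seed = 67, acc = "J")
  target_seq <- fam$proteins$sequence[1]
  iv <- tms_of(fam$topology, fam$proteins$accession[1])
  region <- substr(target_seq, iv[1, "start"], iv[4, "end"])
  donor_seq <- tmskit:::with_seed(8, tmskit:::mutate_sequence(region, 0.15))
  donors <- protein_set("DONOR", donor_seq)
  target <- list(accession = "TARGET", sequence = target_seq)
  hit <- project_domain(donors, target, cfg, domain_acc = "PFX9")
  expect_false(is.null(hit))
  expect_equal(hit$origin, "projected")
  expect_equal(hit$projected_from, "DONOR")
  expect_lt(hit$evalue, cfg$projection_evalue)
  # random target: no projection
  set.seed(2)
  rnd <- list(accession = "RND",
              sequence = random_protein_seq(nchar(target_seq)))
  expect_null(project_domain(donors, rnd, cfg))
  expect_error(project_domain(donors[0, ], target, cfg), "empty")
})

test_that("most common domain requires half the family, ties by E-value", {
  hits <- domain_hits(c("P1", "P2", "P3", "P1", "P2"),
                      c("PF1", "PF1", "PF1", "PF2", "PF2"),
                      rep(1L, 5), rep(50L, 5),
                      c(1e-10, 1e-12, 1e-9, 1e-30, 1e-30))
  members <- c("P1", "P2", "P3", "P4")
  expect_equal(most_common_domain(hits, members), "PF1")
  # below the half-of-family floor: 2 of 5 members
  expect_null(most_common_domain(hits[4:5, ], c(members, "P5")))
  expect_equal(most_common_domain(hits[4:5, ], c("P1", "P2")), "PF2")
  # tie on fraction resolved by lower median E-value
  tie <- domain_hits(c("P1", "P2", "P1", "P2"),
                     c("PF1", "PF1", "PF2", "PF2"),
                     rep(1L, 4), rep(50L, 4),
                     c(1e-5, 1e-5, 1e-30, 1e-30))
  expect_equal(most_common_domain(tie, c("P1", "P2")), "PF2")
})

test_that("related fixture families yield a significant candidate path", {
  cand <- related_pair_run(seed = 301, cfg, max_candidates = 1)
  expect_gte(length(cand), 1L)
  x <- cand[[1]]
  expect_lt(x$evalue_bc, cfg$path_evalue)
  expect_lt(x$evalue_ab, cfg$path_evalue)
  expect_lt(x$evalue_cd, cfg$path_evalue)
  expect_gte(x$n_tms, 3L)
  expect_equal(x$criteria$similarity, "pass")
  expect_gt(x$raw_score, 0)
})

test_that("composition-matched decoy families yield no candidates", {
  cand <- decoy_pair_run(seed = 302, cfg)
  expect_length(cand, 0L)
})

test_that("criteria evaluation follows the 4-of-5 / all-sequence rule", {
  base <- list(criteria = list(similarity = "pass", topology = "pass",
                               domain_overlap = "pass", motif = "pass",
                               structure = "not_applicable"))
  class(base) <- "homology_inference"
  expect_equal(evaluate_criteria(base, FALSE)$verdict, "accept")
  fail_m <- base; fail_m$criteria$motif <- "fail"
  expect_equal(evaluate_criteria(fail_m, FALSE)$verdict, "reject")
  with_s <- fail_m; with_s$criteria$structure <- "pass"
  expect_equal(evaluate_criteria(with_s, TRUE)$verdict, "accept")  # 4 of 5
  man <- base; man$criteria$topology <- "manual"
  expect_equal(evaluate_criteria(man, FALSE)$verdict, "needs review")
})
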