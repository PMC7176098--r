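# Shared test configuration: fewer shuffles than the production default
# keeps the suite fast; tests that probe calibration accuracy set their
# own K explicitly.
test_config <- function(shuffles = 100L, seed = 17L, ...)
  run_config(shuffles = shuffles, seed = seed, ...)

# Fraction of planted TMSs recovered by a prediction, using >= 50%
# reciprocal overlap.
tms_recovery <- function(planted, predicted, accession) {
  p <- tms_of(planted, accession)
  q <- tms_of(predicted, accession)
  if (nrow(p) == 0L) return(NA_real_)
  hit <- 0L
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(q))) {
      ov <- min(p[i, "end"], q[j, "end"]) - max(p[i, "start"], q[j, "start"]) + 1L
      if (ov >= 0.5 * (p[i, "end"] - p[i, "start"] + 1L) &&
          ov >= 0.5 * (q[j, "end"] - q[j, "start"] + 1L)) {
        hit <- hit + 1L
        break
      }
    }
  }
  hit / nrow(p)
}

# internal helpers reached through the package namespace
tms_of <- tmskit:::tms_of
seq_of <- tmskit:::seq_of

# A duplicated-ancestor protein with optional divergence: the canonical
# 4+4 repeat fixture.
duplicated_fixture <- function(seed, p_mut = 0, p_indel = 0, acc = "R1") {
  anc <- make_protein("4", seed = seed, accession = acc)
  fam <- evolve_family(anc, family_spec(events = list("duplicate"),
                                        n_members = 1L, p_mut = p_mut,
                                        p_indel = p_indel,
                                        seed = seed + 7L),
                       prefix = acc)
  # single member named <acc>1
  fam
}

# Predicted topology table for a protein set (decoy annotation helper).
predict_all <- function(proteins, config, window = 19L) {
  rows <- lapply(seq_len(nrow(proteins)), function(i)
    predict_tms(hydropathy_profile(proteins[i, ], window = window), config))
  out <- do.call(rbind, rows)
  class(out) <- c("tms_annotation", "data.frame")
  out
}

# One related-pair transitivity run: benchmark, screening of the two
# anchors, family comparison. Returns the candidate list.
related_pair_run <- function(seed, config, max_candidates = 1) {
  bm <- make_benchmark(seed = seed)
  anchors <- bm$proteins[bm$proteins$accession %in% c("A1", "D1"), ]
  sl <- screen_homologs(anchors, bm$proteins, config)
  compare_families(sl$A1, sl$D1, bm$topology, config,
                   family_a = "FamA", family_d = "FamD",
                   max_candidates = max_candidates)
}

# One decoy-pair run: the two decoy families of a benchmark, annotated
# with predicted topologies, screened and compared against each other.
decoy_pair_run <- function(seed, config) {
  bm <- make_benchmark(seed = seed)
  dec <- bm$proteins[grepl("^X", bm$proteins$accession), ]
  topo <- suppressWarnings(predict_all(dec, config))
  anchors <- dec[dec$accession %in% c("X1_1", "X2_1"), ]
  sl <- screen_homologs(anchors, dec, config)
  suppressWarnings(
    compare_families(sl$X1_1, sl$X2_1, topo, config,
                     family_a = "Decoy1", family_d = "Decoy2"))
}
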