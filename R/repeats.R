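# Detection of internal TMS repeat units: a query protein is cut into
# bundles of k consecutive TMSs (plus flanking loop residues) and
# non-overlapping bundles are aligned against each other; significant
# bundle-vs-bundle alignments evidence an internal repeat such as the
# 4+4 architecture arising from intragenic duplication.

#' Enumerate TMS bundles of a protein
#'
#' One slice per contiguous window of `k` TMSs. A slice spans from
#' `flank` residues before the first TMS to `flank` residues after the
#' last, clamped to the sequence.
#'
#' @param record protein record (list with `accession`, `sequence`).
#' @param topology a [tms_annotation()] covering the protein.
#' @param k bundle size in TMSs.
#' @param flank flanking loop residues included on both sides.
#' @return A data frame of class `bundle_slices` with `protein`,
#'   `tms_first`, `tms_last`, `seq_start`, `seq_end`; zero rows when the
#'   protein has fewer than `k` TMSs.
#' @export
enumerate_bundles <- function(record, topology, k = 4L, flank = 5L) {
  stopifnot(k >= 1L)
  acc <- record$accession
  iv <- tms_of(topology, acc)
  n <- nrow(iv)
  if (n < k) {
    out <- data.frame(protein = character(), tms_first = integer(),
                      tms_last = integer(), seq_start = integer(),
                      seq_end = integer())
    class(out) <- c("bundle_slices", "data.frame")
    return(out)
  }
  L <- nchar(record$sequence)
  first <- seq_len(n - k + 1L)
  out <- data.frame(protein = acc, tms_first = first,
                    tms_last = first + k - 1L,
                    seq_start = pmax(iv[first, "start"] - flank, 1L),
                    seq_end = pmin(iv[first + k - 1L, "end"] + flank, L),
                    stringsAsFactors = FALSE)
  class(out) <- c("bundle_slices", "data.frame")
  out
}

bundle_seq <- function(record, bundle)
  substr(record$sequence, bundle$seq_start, bundle$seq_end)

bundle_label <- function(b)
  sprintf("%s:TMS%d-%d", b$protein, b$tms_first, b$tms_last)

#' Find internal TMS repeats within one protein
#'
#' Aligns every pair of non-overlapping TMS bundles of size `k` (no
#' shared residues) with shuffle-calibrated significance and returns the
#' hits with `evalue <= config$repeat_evalue`, sorted by E-value.
#'
#' @param record protein record (one-row [protein_set()] row or list).
#' @param topology a [tms_annotation()].
#' @param k bundle size in TMSs.
#' @param config a [run_config()].
#' @param flank flanking residues per bundle.
#' @param all_pairs if `TRUE`, return all scored pairs regardless of the
#'   significance threshold (used for rank-based benchmarking).
#' @return A data frame of class `repeat_hits`: bundle coordinates of
#'   both sides, `evalue`, `identity`, `coverage`; attribute
#'   `"alignments"` holds the underlying `local_alignment` objects.
#' @export
find_repeats <- function(record, topology, k = 4L, config = run_config(),
                         flank = 5L, all_pairs = FALSE) {
  bundles <- enumerate_bundles(record, topology, k, flank)
  iv <- tms_of(topology, record$accession)
  hits <- list(); alns <- list()
  if (nrow(bundles) >= 2L) {
    for (i in seq_len(nrow(bundles) - 1L)) {
      for (j in (i + 1L):nrow(bundles)) {
        b1 <- bundles[i, ]; b2 <- bundles[j, ]
        if (b2$tms_first <= b1$tms_last) next  # shared TMSs
        # flanks may meet in a short connecting loop: clip at its midpoint
        # so the two slices never share residues
        core1_end <- iv[b1$tms_last, "end"]
        core2_start <- iv[b2$tms_first, "start"]
        if (b2$seq_start <= b1$seq_end) {
          mid <- (core1_end + core2_start) %/% 2L
          b1$seq_end <- min(b1$seq_end, mid)
          b2$seq_start <- max(b2$seq_start, mid + 1L)
        }
        a <- smith_waterman(bundle_seq(record, b1), bundle_seq(record, b2),
                            config, query = bundle_label(b1),
                            subject = bundle_label(b2), evalue = TRUE)
        hits[[length(hits) + 1L]] <- data.frame(
          protein_1 = b1$protein, tms_first_1 = b1$tms_first,
          tms_last_1 = b1$tms_last, seq_start_1 = b1$seq_start,
          seq_end_1 = b1$seq_end,
          protein_2 = b2$protein, tms_first_2 = b2$tms_first,
          tms_last_2 = b2$tms_last, seq_start_2 = b2$seq_start,
          seq_end_2 = b2$seq_end,
          evalue = a$evalue, identity = a$identity,
          coverage = a$coverage_shorter, stringsAsFactors = FALSE)
        alns[[length(alns) + 1L]] <- a
      }
    }
  }
  finish_repeat_hits(hits, alns, if (all_pairs) Inf else config$repeat_evalue)
}

finish_repeat_hits <- function(hits, alns, threshold) {
  if (length(hits) == 0L) {
    out <- data.frame()
    class(out) <- c("repeat_hits", "data.frame")
    return(out)
  }
  df <- do.call(rbind, hits)
  keep <- which(df$evalue <= threshold)
  ord <- keep[order(df$evalue[keep])]
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignments") <- alns[ord]
  class(out) <- c("repeat_hits", "data.frame")
  out
}

#' Find repeat evidence across two homologous proteins
#'
#' Aligns every bundle of `k` TMSs of protein A against every bundle of
#' protein B, excluding pairs whose TMS ordinal ranges are identical:
#' only offset pairs (e.g. TMS 1-4 of A against TMS 5-8 of B) evidence an
#' internal repeat rather than plain homology.
#'
#' @param record_a,record_b protein records.
#' @param topo_a,topo_b their [tms_annotation()]s.
#' @param k bundle size in TMSs.
#' @param config a [run_config()].
#' @param flank flanking residues per bundle.
#' @param all_pairs if `TRUE`, keep all offset pairs regardless of
#'   significance.
#' @return A `repeat_hits` data frame sorted by E-value.
#' @export
cross_repeat <- function(record_a, topo_a, record_b, topo_b, k = 4L,
                         config = run_config(), flank = 5L,
                         all_pairs = FALSE) {
  ba <- enumerate_bundles(record_a, topo_a, k, flank)
  bb <- enumerate_bundles(record_b, topo_b, k, flank)
  hits <- list(); alns <- list()
  for (i in seq_len(nrow(ba))) {
    for (j in seq_len(nrow(bb))) {
      b1 <- ba[i, ]; b2 <- bb[j, ]
      if (b1$tms_first == b2$tms_first && b1$tms_last == b2$tms_last)
        next  # same ordinal range: homology, not repeat evidence
      a <- smith_waterman(bundle_seq(record_a, b1), bundle_seq(record_b, b2),
                          config, query = bundle_label(b1),
                          subject = bundle_label(b2), evalue = TRUE)
      hits[[length(hits) + 1L]] <- data.frame(
        protein_1 = b1$protein, tms_first_1 = b1$tms_first,
        tms_last_1 = b1$tms_last, seq_start_1 = b1$seq_start,
        seq_end_1 = b1$seq_end,
        protein_2 = b2$protein, tms_first_2 = b2$tms_first,
        tms_last_2 = b2$tms_last, seq_start_2 = b2$seq_start,
        seq_end_2 = b2$seq_end,
        evalue = a$evalue, identity = a$identity,
        coverage = a$coverage_shorter, stringsAsFactors = FALSE)
      alns[[length(alns) + 1L]] <- a
    }
  }
  finish_repeat_hits(hits, alns, if (all_pairs) Inf else config$repeat_evalue)
}

#' Write repeat hits as TSV
#'
#' @param hits a `repeat_hits` data frame.
#' @param path output file.
#' @param config optional [run_config()] for the commented header.
#' @return `path`, invisibly.
#' @export
write_repeats <- function(hits, path, config = NULL) {
  write_tsv_commented(as.data.frame(hits), path, config)
}
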