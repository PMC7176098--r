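# The transitivity engine. Homology between two families is inferred
# through a path A -> B -> C -> D: A and D are characterized members of
# the two families, B and C are homologs of A and D found by screening,
# and the B-C alignment carries the cross-family evidence. Candidate
# paths must be significant throughout (E < path threshold) and the B-C
# alignment must involve at least a repeat unit's worth of TMSs.

#' Screen a database for homologs of each query
#'
#' Every query is aligned against every database record; candidates are
#' kept when the shuffle-calibrated E-value is below
#' `config$screen_evalue` and the alignment covers at least
#' `config$screen_coverage` of the shorter sequence. Surviving hits are
#' made non-redundant at `config$redundancy_identity` (CD-HIT-style
#' greedy reduction).
#'
#' @param queries a [protein_set()] of family members used as anchors.
#' @param database a [protein_set()] to screen (the offline stand-in for
#'   a BLAST screen of a sequence repository).
#' @param config a [run_config()].
#' @return A named list (one element per query accession) of
#'   `homolog_list` objects: `query`, `hits` (a [protein_set()]),
#'   `evalue` (named), and `alignments`.
#' @export
screen_homologs <- function(queries, database, config = run_config()) {
  if (nrow(database) == 0L) stop("empty database")
  out <- list()
  for (qi in seq_len(nrow(queries))) {
    qacc <- queries$accession[qi]
    qseq <- queries$sequence[qi]
    # one vectorized score-only pass over the database, then full
    # alignments and shuffle calibration only for plausible candidates
    quick <- pmax(score_many(database$sequence, qseq, config), 0)
    keep <- integer(0); evs <- numeric(0); alns <- list()
    for (di in seq_len(nrow(database))) {
      if (quick[di] <= 0 ||
          likely_insignificant(quick[di], nchar(qseq),
                               nchar(database$sequence[di]), config,
                               config$screen_evalue))
        next
      a <- smith_waterman(qseq, database$sequence[di], config,
                          query = qacc, subject = database$accession[di])
      if (a$coverage_shorter < config$screen_coverage)
        next  # cannot pass; skip the shuffle cost
      ev <- shuffle_evalue(qseq, database$sequence[di], a$raw_score, config)
      if (ev$evalue < config$screen_evalue) {
        a$evalue <- ev$evalue; a$z_score <- ev$z_score
        a$shuffles <- ev$fit$n_samples
        keep <- c(keep, di)
        evs <- c(evs, ev$evalue)
        alns[[length(alns) + 1L]] <- a
      }
    }
    hits <- database[keep, , drop = FALSE]
    class(hits) <- c("protein_set", "data.frame")
    names(evs) <- hits$accession
    if (nrow(hits) > 1L) {
      nr <- reduce_redundancy(hits, config$redundancy_identity, config)
      sel <- hits$accession %in% nr$accession
      hits <- nr; evs <- evs[sel]; alns <- alns[sel]
    }
    hl <- list(query = qacc, query_sequence = qseq, hits = hits,
               evalue = evs, alignments = alns)
    class(hl) <- "homolog_list"
    out[[qacc]] <- hl
    tk_log("screen ", qacc, ": ", nrow(hits), " homologs retained")
  }
  out
}

#' Map corresponding TMSs through a pairwise alignment
#'
#' TMS i of the query pairs with TMS j of the subject when their images
#' in alignment columns overlap by at least `min_overlap_fraction` of the
#' shorter of the two segments. Crossing candidate pairs are resolved
#' greedily by decreasing column overlap so the accepted pairs are
#' colinear (strictly increasing ordinals on both sides).
#'
#' @param aln a `local_alignment` (query = B, subject = C).
#' @param topo_b,topo_c [tms_annotation()]s for the two proteins.
#' @param min_overlap_fraction overlap rule; default 0.5.
#' @return A list of class `tms_correspondence`: `pairs` (data frame
#'   `tms_b`, `tms_c`, `overlap_columns`) and `n_aligned_tms`.
#' @export
map_tms_correspondence <- function(aln, topo_b, topo_c,
                                   min_overlap_fraction = 0.5) {
  empty <- list(pairs = data.frame(tms_b = integer(), tms_c = integer(),
                                   overlap_columns = integer()),
                n_aligned_tms = 0L)
  class(empty) <- "tms_correspondence"
  if (!nzchar(aln$q_aln)) return(empty)
  qc <- strsplit(aln$q_aln, "")[[1]]
  sc <- strsplit(aln$s_aln, "")[[1]]
  qres <- ifelse(qc != "-", aln$q_start - 1L + cumsum(qc != "-"), NA_integer_)
  sres <- ifelse(sc != "-", aln$s_start - 1L + cumsum(sc != "-"), NA_integer_)
  ivb <- tms_of(topo_b, aln$query)
  ivc <- tms_of(topo_c, aln$subject)
  if (nrow(ivb) == 0L || nrow(ivc) == 0L) return(empty)
  cols_b <- lapply(seq_len(nrow(ivb)), function(i)
    which(!is.na(qres) & qres >= ivb[i, "start"] & qres <= ivb[i, "end"]))
  cols_c <- lapply(seq_len(nrow(ivc)), function(j)
    which(!is.na(sres) & sres >= ivc[j, "start"] & sres <= ivc[j, "end"]))
  cand <- list()
  for (i in seq_len(nrow(ivb))) {
    for (j in seq_len(nrow(ivc))) {
      ov <- length(intersect(cols_b[[i]], cols_c[[j]]))
      shorter <- min(ivb[i, "end"] - ivb[i, "start"] + 1L,
                     ivc[j, "end"] - ivc[j, "start"] + 1L)
      if (ov >= min_overlap_fraction * shorter)
        cand[[length(cand) + 1L]] <- c(i, j, ov)
    }
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  acc <- matrix(integer(0), ncol = 3)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (i %in% acc[, 1] || j %in% acc[, 2]) next
    if (nrow(acc) && any((i - acc[, 1]) * (j - acc[, 2]) <= 0))
      next  # would cross an accepted pair
    acc <- rbind(acc, cand[r, , drop = FALSE])
  }
  acc <- acc[order(acc[, 1]), , drop = FALSE]
  out <- list(pairs = data.frame(tms_b = acc[, 1], tms_c = acc[, 2],
                                 overlap_columns = acc[, 3]),
              n_aligned_tms = nrow(acc))
  class(out) <- "tms_correspondence"
  out
}

# Count TMSs of a protein whose interval overlaps [lo, hi] by at least
# half the TMS length.
count_tms_in_span <- function(topology, accession, lo, hi) {
  iv <- tms_of(topology, accession)
  if (nrow(iv) == 0L || hi < lo) return(0L)
  ov <- pmin(iv[, "end"], hi) - pmax(iv[, "start"], lo) + 1L
  sum(ov >= 0.5 * (iv[, "end"] - iv[, "start"] + 1L))
}

#' Check domain overlap within a B-C alignment
#'
#' Passes when, on each side, the family's characteristic domain (the
#' lowest-E-value hit supplied for that protein) intersects the aligned
#' span over at least `min_tms` TMSs -- or over the full domain when the
#' domain itself covers fewer than `min_tms` TMSs. Clan identity (hits on
#' the two sides with different accessions in the same clan) is recorded
#' separately as supporting evidence.
#'
#' @param aln the B-C `local_alignment`.
#' @param hits_b,hits_c [domain_hits()] for the two proteins.
#' @param topo_b,topo_c their [tms_annotation()]s.
#' @param min_tms overlap rule, default 3.
#' @return A list with `pass`, `reason`, `clan_support`.
#' @export
check_domain_overlap <- function(aln, hits_b, hits_c, topo_b, topo_c,
                                 min_tms = 3L) {
  hb <- hits_b[hits_b$protein == aln$query, , drop = FALSE]
  hc <- hits_c[hits_c$protein == aln$subject, , drop = FALSE]
  if (nrow(hb) == 0L && nrow(hc) == 0L)
    return(list(pass = FALSE, reason = "no domains", clan_support = FALSE))
  side <- function(h, topo, acc, span_lo, span_hi) {
    if (nrow(h) == 0L) return(list(ok = FALSE, why = "no domain hit"))
    h <- h[which.min(h$evalue), ]
    lo <- max(h$env_start, span_lo); hi <- min(h$env_end, span_hi)
    if (hi < lo) return(list(ok = FALSE, why = "domain outside alignment"))
    n_dom <- count_tms_in_span(topo, acc, h$env_start, h$env_end)
    n_ov <- count_tms_in_span(topo, acc, lo, hi)
    if (n_dom < min_tms) {
      ok <- lo <= h$env_start && hi >= h$env_end  # full small domain inside
      return(list(ok = ok,
                  why = if (ok) "full small domain" else "small domain cut"))
    }
    list(ok = n_ov >= min_tms,
         why = paste0(n_ov, " TMS in domain/alignment intersection"))
  }
  b <- side(hb, topo_b, aln$query, aln$q_start, aln$q_end)
  c_ <- side(hc, topo_c, aln$subject, aln$s_start, aln$s_end)
  clan <- FALSE
  if (nrow(hb) && nrow(hc)) {
    for (i in seq_len(nrow(hb))) for (j in seq_len(nrow(hc)))
      if (!is.na(hb$clan[i]) && !is.na(hc$clan[j]) &&
          hb$clan[i] == hc$clan[j] && hb$domain_acc[i] != hc$domain_acc[j])
        clan <- TRUE
  }
  list(pass = b$ok && c_$ok,
       reason = paste0("B: ", b$why, "; C: ", c_$why),
       clan_support = clan)
}

#' Project a domain onto a protein without a direct hit
#'
#' Aligns each donor region (the envelope slice of a direct hit in a
#' family member) against the target; if any alignment is significant
#' (`E < config$projection_evalue`) and covers at least
#' `config$projection_coverage` of the donor region, a projected
#' [domain_hits()] row is created at the target's aligned span, recording
#' the best donor.
#'
#' @param donor_regions a [protein_set()] whose sequences are the direct
#'   hit envelope slices (accessions = donor protein accessions).
#' @param target_record the protein to annotate (list with `accession`,
#'   `sequence`).
#' @param config a [run_config()].
#' @param domain_acc,clan identity of the domain being projected.
#' @return A one-row [domain_hits()] with `origin = "projected"`, or
#'   `NULL` when no projection is significant.
#' @export
project_domain <- function(donor_regions, target_record,
                           config = run_config(),
                           domain_acc = "domain", clan = NA_character_) {
  if (nrow(donor_regions) == 0L) stop("empty donor set")
  best <- NULL
  for (i in seq_len(nrow(donor_regions))) {
    dseq <- donor_regions$sequence[i]
    a <- smith_waterman(dseq, target_record$sequence, config,
                        query = donor_regions$accession[i],
                        subject = target_record$accession)
    if (a$raw_score <= 0) next
    cov_donor <- (a$q_end - a$q_start + 1L) / nchar(dseq)
    if (cov_donor < config$projection_coverage) next
    ev <- shuffle_evalue(dseq, target_record$sequence, a$raw_score, config)
    if (ev$evalue < config$projection_evalue &&
        (is.null(best) || ev$evalue < best$evalue)) {
      best <- list(evalue = ev$evalue, donor = donor_regions$accession[i],
                   s_start = a$s_start, s_end = a$s_end)
    }
  }
  if (is.null(best)) return(NULL)
  domain_hits(protein = target_record$accession, domain_acc = domain_acc,
              clan = clan, env_start = best$s_start, env_end = best$s_end,
              evalue = best$evalue, origin = "projected",
              projected_from = best$donor)
}

#' Most common domain of a family
#'
#' The domain accession hit in the highest fraction of family members,
#' required to be present in at least `min_fraction` of them; ties are
#' broken by the lower median E-value.
#'
#' @param hits a [domain_hits()] table for the family members.
#' @param members character vector of the family's accessions.
#' @param min_fraction required member fraction, default 0.5.
#' @return The domain accession, or `NULL` when none qualifies.
#' @export
most_common_domain <- function(hits, members, min_fraction = 0.5) {
  h <- hits[hits$protein %in% members, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  frac <- vapply(split(h, h$domain_acc),
                 function(d) length(unique(d$protein)) / length(members), 0)
  frac <- frac[frac >= min_fraction]
  if (length(frac) == 0L) return(NULL)
  top <- names(frac)[frac == max(frac)]
  if (length(top) > 1L) {
    med <- vapply(top, function(d) median(h$evalue[h$domain_acc == d]), 0)
    top <- top[which.min(med)]
  }
  top
}

#' Compare two families through their homolog lists
#'
#' Aligns every B (homolog of the family-A anchor) against every C
#' (homolog of the family-D anchor). A pair is a candidate transitivity
#' path when all three alignments A-B, B-C and C-D are significant below
#' `config$path_evalue` and the B-C alignment aligns at least
#' `config$min_tms` corresponding TMSs (matched colinear pairs under the
#' 50% overlap rule -- the stricter reading of "TMSs included in the
#' alignment"; the per-protein TMS span counts are also reported).
#' Candidates are sorted by (B-C E-value, aligned TMSs desc, identity
#' desc).
#'
#' @param list_a,list_d `homolog_list`s (from [screen_homologs()]) for
#'   the anchors of families A and D.
#' @param topology [tms_annotation()] covering the homologs.
#' @param config a [run_config()].
#' @param family_a,family_d family labels recorded on the inferences.
#' @param domains optional [domain_hits()]; when supplied the domain
#'   overlap criterion is evaluated per candidate.
#' @param max_candidates stop once this many candidates are found (e.g.
#'   1 when only the existence of a path matters); default unlimited.
#' @return A list of `homology_inference` objects (class
#'   `homology_candidates`), each with the path accessions, the three
#'   alignments, the TMS correspondence, criteria flags and the raw
#'   confidence score.
#' @export
compare_families <- function(list_a, list_d, topology, config = run_config(),
                             family_a = "FamilyA", family_d = "FamilyD",
                             domains = NULL, max_candidates = Inf) {
  cands <- list()
  for (bi in seq_len(nrow(list_a$hits))) {
    if (length(cands) >= max_candidates) break
    bacc <- list_a$hits$accession[bi]
    if (!bacc %in% topology$protein) {
      warning("no topology for ", bacc, "; pair skipped")
      next
    }
    ev_ab <- list_a$evalue[[bacc]]
    if (ev_ab >= config$path_evalue) next
    for (ci in seq_len(nrow(list_d$hits))) {
      cacc <- list_d$hits$accession[ci]
      if (cacc == bacc || cacc == list_a$query || bacc == list_d$query)
        next  # degenerate path: B and C must be distinct intermediates
      if (!cacc %in% topology$protein) {
        warning("no topology for ", cacc, "; pair skipped")
        next
      }
      ev_cd <- list_d$evalue[[cacc]]
      if (ev_cd >= config$path_evalue) next
      bc <- smith_waterman(list_a$hits$sequence[bi], list_d$hits$sequence[ci],
                           config, query = bacc, subject = cacc)
      if (bc$raw_score <= 0) next
      # cheap checks first: TMS correspondence, then a constant-based
      # E-value prescreen, and only then the shuffle calibration
      corr <- map_tms_correspondence(bc, topology, topology)
      if (corr$n_aligned_tms < config$min_tms) next
      if (likely_insignificant(bc$raw_score, nchar(list_a$hits$sequence[bi]),
                               nchar(list_d$hits$sequence[ci]), config,
                               config$path_evalue))
        next
      ev_bc <- shuffle_evalue(list_a$hits$sequence[bi],
                              list_d$hits$sequence[ci], bc$raw_score, config)
      bc$evalue <- ev_bc$evalue; bc$z_score <- ev_bc$z_score
      bc$shuffles <- ev_bc$fit$n_samples
      bc$evalue_flagged <- ev_bc$flagged
      if (bc$evalue >= config$path_evalue) next
      crit <- list(similarity = "pass", topology = "manual",
                   domain_overlap = "not_applicable",
                   motif = "not_applicable", structure = "not_applicable")
      if (!is.null(domains)) {
        dom <- check_domain_overlap(bc, domains, domains, topology, topology)
        crit$domain_overlap <- if (dom$pass) "pass" else "fail"
      }
      inf <- list(family_a = family_a, family_d = family_d,
                  path = c(A = list_a$query, B = bacc, C = cacc,
                           D = list_d$query),
                  evalue_ab = ev_ab, evalue_bc = bc$evalue,
                  evalue_cd = ev_cd,
                  aln_bc = bc, correspondence = corr,
                  n_tms = corr$n_aligned_tms,
                  n_tms_span_b = count_tms_in_span(topology, bacc,
                                                   bc$q_start, bc$q_end),
                  n_tms_span_c = count_tms_in_span(topology, cacc,
                                                   bc$s_start, bc$s_end),
                  criteria = crit,
                  raw_score = confidence_score(corr$n_aligned_tms,
                                               min(bc$evalue, 1)),
                  norm_score = NA_real_, level = NA_character_,
                  verdict = NA_character_)
      class(inf) <- "homology_inference"
      cands[[length(cands) + 1L]] <- inf
      if (length(cands) >= max_candidates) break
    }
  }
  if (length(cands)) {
    ord <- order(vapply(cands, `[[`, 0, "evalue_bc"),
                 -vapply(cands, `[[`, 0L, "n_tms"),
                 -vapply(cands, function(x) x$aln_bc$identity, 0))
    cands <- cands[ord]
  }
  class(cands) <- "homology_candidates"
  cands
}

#' @export
print.homology_inference <- function(x, ...) {
  cat(sprintf("homology_inference %s -> %s\n", x$family_a, x$family_d))
  cat(sprintf("  path %s -> %s -> %s -> %s\n", x$path["A"], x$path["B"],
              x$path["C"], x$path["D"]))
  cat(sprintf("  E: AB %.2g | BC %.2g | CD %.2g;  %d aligned TMSs\n",
              x$evalue_ab, x$evalue_bc, x$evalue_cd, x$n_tms))
  cat("  criteria:", paste(names(x$criteria), unlist(x$criteria),
                           sep = "=", collapse = " "), "\n")
  if (!is.na(x$verdict)) cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' @export
print.homology_candidates <- function(x, ...) {
  cat("homology_candidates:", length(x), "candidate path(s)\n")
  for (i in seq_along(x))
    cat(sprintf("  %d. %s-%s via %s/%s  E_bc=%.2g  n_tms=%d\n", i,
                x[[i]]$family_a, x[[i]]$family_d, x[[i]]$path["B"],
                x[[i]]$path["C"], x[[i]]$evalue_bc, x[[i]]$n_tms))
  invisible(x)
}

#' Final verdict over the five homology criteria
#'
#' Without 3D structures, all four sequence criteria (similarity,
#' topology congruence, domain overlap, motif conservation) must pass for
#' acceptance; with structures available, at least 4 of the 5 criteria
#' must pass. Criteria still flagged `manual` block an automatic accept
#' and mark the inference as needing review.
#'
#' @param inference a `homology_inference`.
#' @param structures_available whether criterion 5 applies.
#' @return The inference with `verdict` set to `"accept"`, `"reject"` or
#'   `"needs review"`.
#' @export
evaluate_criteria <- function(inference, structures_available = FALSE) {
  cr <- unlist(inference$criteria)
  seq_cr <- cr[c("similarity", "topology", "domain_overlap", "motif")]
  if (structures_available) {
    n_pass <- sum(cr == "pass")
    n_open <- sum(cr %in% c("manual", "not_applicable"))
    inference$verdict <-
      if (n_pass >= 4) "accept"
      else if (n_pass + n_open >= 4) "needs review"
      else "reject"
  } else {
    if (all(seq_cr == "pass")) inference$verdict <- "accept"
    else if (any(seq_cr == "fail")) inference$verdict <- "reject"
    else inference$verdict <- "needs review"
  }
  inference
}

#' Write an inference report as TSV
#'
#' One row per candidate path: families, path accessions, the three
#' E-values, aligned TMS counts, criteria flags and verdict.
#'
#' @param candidates a `homology_candidates` list.
#' @param path output file.
#' @param config optional [run_config()] for the header.
#' @return `path`, invisibly.
#' @export
write_inference_report <- function(candidates, path, config = NULL) {
  df <- do.call(rbind, lapply(candidates, function(x)
    data.frame(family_a = x$family_a, A = x$path["A"], B = x$path["B"],
               C = x$path["C"], D = x$path["D"], family_d = x$family_d,
               evalue_ab = x$evalue_ab, evalue_bc = x$evalue_bc,
               evalue_cd = x$evalue_cd, n_tms = x$n_tms,
               n_tms_span_b = x$n_tms_span_b, n_tms_span_c = x$n_tms_span_c,
               criteria = paste(names(x$criteria), unlist(x$criteria),
                                sep = "=", collapse = ","),
               raw_score = x$raw_score, norm_score = x$norm_score,
               level = x$level, verdict = x$verdict,
               stringsAsFactors = FALSE, row.names = NULL)))
  write_tsv_commented(df, path, config)
}
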