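# Synthetic membrane-protein and family generator. Plants TMS topologies
# (e.g. "4+4" for an intragenic duplication of a 4-TMS unit, "3+4" after
# loss of the N-terminal TMS) and evolves families by per-site
# substitution and loop-confined indels, keeping the planted TMS
# coordinates exact so they can serve as ground truth.

# Residue pools with sampling weights chosen to emulate real membrane
# proteins: TM helices dominated by strongly hydrophobic residues
# (window-averaged Kyte-Doolittle ~3.7), loops enriched in small polar
# residues with some charge (~-1.9).
.hydrophobic_pool <- c(I = 0.28, L = 0.28, V = 0.22, F = 0.10, A = 0.07,
                       M = 0.05)
.hydrophilic_pool <- c(G = 0.18, S = 0.18, T = 0.14, P = 0.12, N = 0.07,
                       Q = 0.07, D = 0.06, E = 0.06, K = 0.05, R = 0.04,
                       H = 0.03)

sample_pool <- function(pool, n)
  sample(names(pool), n, replace = TRUE, prob = pool)

#' Generate one synthetic membrane protein from a topology string
#'
#' Builds a protein as alternating hydrophilic loops (8-40 residues,
#' weighted sample of small polar and charged residues) and hydrophobic
#' TMS segments (18-24 residues, weighted sample of I L V F A M). The
#' topology string gives TMS counts per repeat unit separated by `+`
#' (`"4+4"`, `"3+4"`, `"4+2+4"`); the total TMS count is the sum.
#' Planted intervals are returned with `source = "planted"` and are
#' exact.
#'
#' @param topology topology string, e.g. `"4+4"`.
#' @param seed integer seed; the same seed reproduces the same protein.
#' @param accession identifier for the record.
#' @return A list with elements `proteins` (a one-row [protein_set()])
#'   and `topology` (a [tms_annotation()]).
#' @export
make_protein <- function(topology, seed = 1L, accession = "SYN1") {
  parts <- suppressWarnings(as.integer(strsplit(topology, "+", fixed = TRUE)[[1]]))
  if (length(parts) == 0L || anyNA(parts) || any(parts < 1L))
    stop("malformed topology string: ", topology)
  n_tms <- sum(parts)
  with_seed(seed, {
    pieces <- character(0)
    st <- integer(0); en <- integer(0)
    pos <- 0L
    add_loop <- function() {
      len <- sample(8:40, 1L)
      paste(sample_pool(.hydrophilic_pool, len), collapse = "")
    }
    for (i in seq_len(n_tms)) {
      lp <- add_loop()
      pieces <- c(pieces, lp); pos <- pos + nchar(lp)
      len <- sample(18:24, 1L)
      tms <- paste(sample_pool(.hydrophobic_pool, len),
                   collapse = "")
      pieces <- c(pieces, tms)
      st <- c(st, pos + 1L); en <- c(en, pos + len)
      pos <- pos + len
    }
    pieces <- c(pieces, add_loop())
    prot <- protein_set(accession, paste(pieces, collapse = ""),
                        description = paste0("synthetic ", topology))
    list(proteins = prot,
         topology = tms_annotation(rep(accession, n_tms), st, en,
                                   source = "planted", proteins = prot))
  })
}

#' Family specification for the synthetic generator
#'
#' @param events ordered list of evolutionary events applied to the
#'   ancestor before divergence. Each element is either a string
#'   (`"duplicate"`, `"lose_n_terminal_tms"`, `"fuse"`) or a list
#'   `list("insert_central_tms", n)`.
#' @param n_members members to generate.
#' @param p_mut per-site substitution probability in \[0, 1).
#' @param p_indel per-loop indel probability in \[0, 1).
#' @param seed integer seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(events = list(), n_members = 3L, p_mut = 0.2,
                        p_indel = 0.05, seed = 1L) {
  stopifnot(p_mut >= 0, p_mut < 1, p_indel >= 0, p_indel < 1, n_members >= 1)
  out <- list(events = events, n_members = as.integer(n_members),
              p_mut = p_mut, p_indel = p_indel, seed = as.integer(seed))
  class(out) <- "family_spec"
  out
}

# --- events -----------------------------------------------------------

apply_event <- function(member, event) {
  ev <- if (is.character(event)) event else event[[1]]
  seqc <- member$proteins$sequence[1]
  acc <- member$proteins$accession[1]
  iv <- tms_of(member$topology, acc)
  switch(ev,
    duplicate = {
      L <- nchar(seqc)
      seq2 <- paste0(seqc, seqc)
      st <- c(iv[, "start"], iv[, "start"] + L)
      en <- c(iv[, "end"], iv[, "end"] + L)
      remake_member(acc, seq2, st, en)
    },
    lose_n_terminal_tms = {
      if (nrow(iv) < 2L) stop("cannot lose the only TMS")
      cut <- iv[1, "end"]  # remove through the first TMS; its loop stays N-terminal
      seq2 <- substr(seqc, cut + 1L, nchar(seqc))
      remake_member(acc, seq2, iv[-1, "start"] - cut, iv[-1, "end"] - cut)
    },
    insert_central_tms = {
      n <- event[[2]]
      mid <- nrow(iv) %/% 2L
      at <- iv[mid, "end"] + 4L  # inside the loop after the central TMS
      ins <- make_protein(as.character(n), seed = nchar(seqc) + n,
                          accession = "INS")
      ins_seq <- ins$proteins$sequence[1]
      ins_iv <- tms_of(ins$topology, "INS")
      w <- nchar(ins_seq)
      seq2 <- paste0(substr(seqc, 1L, at), ins_seq,
                     substr(seqc, at + 1L, nchar(seqc)))
      st <- c(iv[seq_len(mid), "start"], ins_iv[, "start"] + at,
              iv[-seq_len(mid), "start"] + w)
      en <- c(iv[seq_len(mid), "end"], ins_iv[, "end"] + at,
              iv[-seq_len(mid), "end"] + w)
      remake_member(acc, seq2, st, en)
    },
    fuse = member,  # fusion with an empty partner is the identity here
    stop("unknown event: ", ev))
}

remake_member <- function(acc, seqc, st, en, source = "planted") {
  prot <- protein_set(acc, seqc)
  list(proteins = prot,
       topology = tms_annotation(rep(acc, length(st)), st, en,
                                 source = source, proteins = prot))
}

# --- divergence -------------------------------------------------------

# BLOSUM-weighted substitution kernel: P(b | a) proportional to
# 2^(s(a,b)/3) over the 20 standard residues, b != a.
.mutation_kernel <- local({
  kernel <- NULL
  function() {
    if (is.null(kernel)) {
      aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V")
      mat <- get_submatrix("BLOSUM50")[aa, aa]
      k <- 2^(mat / 3)
      diag(k) <- 0
      kernel <<- sweep(k, 1, rowSums(k), "/")
    }
    kernel
  }
})

mutate_sequence <- function(seqc, p_mut) {
  if (p_mut <= 0) return(seqc)
  chars <- strsplit(seqc, "")[[1]]
  hit <- which(runif(length(chars)) < p_mut & chars %in% rownames(.mutation_kernel()))
  for (i in hit) {
    k <- .mutation_kernel()[chars[i], ]
    chars[i] <- sample(colnames(.mutation_kernel()), 1L, prob = k)
  }
  paste(chars, collapse = "")
}

# Apply loop-confined indels; returns updated sequence and shifted TMSs.
apply_indels <- function(seqc, iv, p_indel) {
  if (p_indel <= 0 || nrow(iv) == 0L)
    return(list(seq = seqc, iv = iv))
  # loops: [prev_end+1, next_start-1], including terminal loops
  bounds <- rbind(c(1L, iv[1, "start"] - 1L),
                  if (nrow(iv) > 1L)
                    cbind(iv[-nrow(iv), "end"] + 1L, iv[-1, "start"] - 1L),
                  c(iv[nrow(iv), "end"] + 1L, nchar(seqc)))
  # process loops right-to-left so earlier coordinates stay valid
  for (li in rev(seq_len(nrow(bounds)))) {
    lo <- bounds[li, 1]; hi <- bounds[li, 2]
    if (hi - lo + 1L < 4L || runif(1) >= p_indel) next
    len <- rgeom(1, 0.5) + 1L
    if (runif(1) < 0.5) {  # insertion of hydrophilic residues
      at <- sample(lo:hi, 1L)
      ins <- paste(sample_pool(.hydrophilic_pool, len),
                   collapse = "")
      seqc <- paste0(substr(seqc, 1L, at), ins,
                     substr(seqc, at + 1L, nchar(seqc)))
      shift <- iv[, "start"] > at
      iv[shift, "start"] <- iv[shift, "start"] + len
      iv[shift, "end"] <- iv[shift, "end"] + len
    } else {  # deletion confined to the loop, keep >= 2 residues
      len <- min(len, hi - lo - 1L)
      if (len < 1L) next
      at <- sample(lo:(hi - len), 1L)
      seqc <- paste0(substr(seqc, 1L, at - 1L),
                     substr(seqc, at + len, nchar(seqc)))
      shift <- iv[, "start"] > at
      iv[shift, "start"] <- iv[shift, "start"] - len
      iv[shift, "end"] <- iv[shift, "end"] - len
    }
  }
  list(seq = seqc, iv = iv)
}

#' @importFrom stats rgeom
NULL

#' Evolve a synthetic family from an ancestor
#'
#' Applies the family specification's ordered events (duplication, loss of the N-terminal
#' TMS, central TMS insertion) to the ancestor, then generates members by
#' independent per-site substitution (replacements drawn with
#' BLOSUM-exchangeability weights) and geometric-length indels confined
#' to loops, so planted TMS intervals remain exact.
#'
#' @param ancestor output of [make_protein()] (list with `proteins` and
#'   `topology`).
#' @param spec a [family_spec()].
#' @param prefix accession prefix for the members.
#' @param family family label recorded on the members.
#' @return A list with `proteins` (a [protein_set()]) and `topology` (a
#'   planted [tms_annotation()]) covering all members.
#' @export
evolve_family <- function(ancestor, spec, prefix = "M", family = NA_character_) {
  founder <- ancestor
  for (ev in spec$events) founder <- apply_event(founder, ev)
  fseq <- founder$proteins$sequence[1]
  fiv <- tms_of(founder$topology, founder$proteins$accession[1])
  with_seed(spec$seed, {
    members <- lapply(seq_len(spec$n_members), function(i) {
      seqc <- mutate_sequence(fseq, spec$p_mut)
      ind <- apply_indels(seqc, fiv, spec$p_indel)
      list(acc = paste0(prefix, i), seq = ind$seq, iv = ind$iv)
    })
    prot <- protein_set(vapply(members, `[[`, "", "acc"),
                        vapply(members, `[[`, "", "seq"),
                        family = family)
    topo <- tms_annotation(
      unlist(lapply(members, function(m) rep(m$acc, nrow(m$iv)))),
      unlist(lapply(members, function(m) m$iv[, "start"])),
      unlist(lapply(members, function(m) m$iv[, "end"])),
      source = "planted", proteins = prot)
    list(proteins = prot, topology = topo)
  })
}

#' Build a labeled benchmark of related families plus decoys
#'
#' Emulates a positive/negative control design: two families that share a
#' duplicated 4-TMS ancestral unit (the positive pair) plus
#' composition-matched decoy families obtained by residue-shuffling real
#' fixture members, which preserves composition while destroying
#' homology. Truth labels are attached as the `family` column
#' (`"FamA"`, `"FamD"`, `"Decoy1"`, ...).
#'
#' @param seed integer seed.
#' @param unit_tms TMS count of the ancestral unit.
#' @param p_divergence total per-site divergence planted between the two
#'   related families (half applied on each side of the ancestor).
#' @param p_within per-site divergence of members within each family.
#' @param n_members members per family.
#' @param n_decoy_families number of shuffled decoy families.
#' @return A list with `proteins`, `topology`, and `truth` (data frame
#'   with `accession`, `family`, `related` flag).
#' @export
make_benchmark <- function(seed = 1L, unit_tms = 4L, p_divergence = 0.4,
                           p_within = 0.15, n_members = 3L,
                           n_decoy_families = 2L) {
  anc <- make_protein(as.character(unit_tms), seed = child_seed(seed, 1L),
                      accession = "ANC")
  dupl <- apply_event(anc, "duplicate")
  # family founders diverge from the shared duplicated ancestor, then
  # members diverge from their founder
  half <- p_divergence / 2
  founderA <- with_seed(child_seed(seed, 2L),
    remake_member("ANC", mutate_sequence(dupl$proteins$sequence[1], half),
                  tms_of(dupl$topology, "ANC")[, "start"],
                  tms_of(dupl$topology, "ANC")[, "end"]))
  founderD <- with_seed(child_seed(seed, 3L),
    remake_member("ANC", mutate_sequence(dupl$proteins$sequence[1], half),
                  tms_of(dupl$topology, "ANC")[, "start"],
                  tms_of(dupl$topology, "ANC")[, "end"]))
  famA <- evolve_family(founderA, family_spec(
    n_members = n_members, p_mut = p_within,
    p_indel = 0.05, seed = child_seed(seed, 4L)), prefix = "A", family = "FamA")
  famD <- evolve_family(founderD, family_spec(
    n_members = n_members, p_mut = p_within,
    p_indel = 0.05, seed = child_seed(seed, 5L)), prefix = "D", family = "FamD")
  # decoys: each decoy family descends from a composition-preserving
  # shuffle of a real founder, so members are genuinely homologous within
  # the decoy family but unrelated (beyond composition) to everything else
  decoys <- with_seed(child_seed(seed, 6L), {
    src <- c(founderA$proteins$sequence, founderD$proteins$sequence)
    out <- list()
    for (f in seq_len(n_decoy_families)) {
      s <- src[(f - 1L) %% length(src) + 1L]
      dfound <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
      seqs <- vapply(seq_len(n_members), function(i)
        mutate_sequence(dfound, p_within), "")
      out[[f]] <- protein_set(paste0("X", f, "_", seq_len(n_members)), seqs,
                              family = paste0("Decoy", f))
    }
    out
  })
  all_prot <- rbind(famA$proteins, famD$proteins,
                    do.call(rbind, decoys))
  class(all_prot) <- c("protein_set", "data.frame")
  topo <- rbind(famA$topology, famD$topology)
  class(topo) <- c("tms_annotation", "data.frame")
  truth <- data.frame(accession = all_prot$accession,
                      family = all_prot$family,
                      related = all_prot$family %in% c("FamA", "FamD"),
                      stringsAsFactors = FALSE)
  list(proteins = all_prot, topology = topo, truth = truth)
}
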