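#' Construct a protein set
#'
#' A `protein_set` is the package's container for protein sequence records:
#' a data frame with columns `accession`, `description`, `sequence` and
#' `family`. Sequences are uppercase strings over the 20-letter amino-acid
#' alphabet; the ambiguity codes B, Z, U, O and X are tolerated (they are
#' scored as X during alignment) but gap characters are rejected.
#'
#' @param accession character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param description optional free-text descriptions.
#' @param family optional family labels (e.g. TC numbers).
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(accession, sequence, description = "", family = NA_character_) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  if (length(accession) != length(sequence))
    stop("accession and sequence must have equal length")
  if (anyDuplicated(accession))
    stop("duplicate accessions: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for: ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  bad <- grepl("[-.*]", sequence)
  if (any(bad))
    stop("gap or stop characters in sequence of: ",
         paste(accession[bad], collapse = ", "))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYBZXUO]*$", sequence)
  if (any(!ok))
    stop("non amino-acid characters in sequence of: ",
         paste(accession[!ok], collapse = ", "))
  if (any(grepl("X", sequence, fixed = TRUE)))
    tk_log("sequences contain X residues: ",
           paste(accession[grepl("X", sequence, fixed = TRUE)], collapse = ", "))
  df <- data.frame(accession = accession,
                   description = rep_len(as.character(description), length(accession)),
                   sequence = sequence,
                   family = rep_len(as.character(family), length(accession)),
                   stringsAsFactors = FALSE)
  class(df) <- c("protein_set", "data.frame")
  df
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "records\n")
  if (nrow(x)) {
    show <- utils::head(x, 6)
    cat(sprintf("  %-20s %6s  %s\n", show$accession, nchar(show$sequence),
                ifelse(is.na(show$family), "", show$family)), sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

# Fetch one sequence by accession.
seq_of <- function(proteins, accession) {
  i <- match(accession, proteins$accession)
  if (is.na(i)) stop("unknown accession: ", accession)
  proteins$sequence[i]
}

#' Construct a TMS annotation table
#'
#' Ordered transmembrane-segment (TMS) intervals on one or more proteins.
#' Coordinates are 1-based inclusive residue positions. Intervals for a
#' protein must be sorted and non-overlapping; when `proteins` is supplied,
#' intervals are checked against sequence bounds.
#'
#' @param protein character vector of accessions (one entry per interval).
#' @param start,end integer vectors of interval bounds, 1-based inclusive.
#' @param source provenance of the annotation: `"predicted"`, `"imported"`
#'   or `"planted"`.
#' @param proteins optional [protein_set()] used for bounds checking.
#' @return A data frame of class `tms_annotation` with columns `protein`,
#'   `tms` (ordinal within protein), `start`, `end`, `source`.
#' @export
tms_annotation <- function(protein, start, end,
                           source = c("predicted", "imported", "planted"),
                           proteins = NULL) {
  source <- match.arg(source)
  protein <- as.character(protein)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(protein) == length(start), length(start) == length(end))
  if (length(start) && any(start < 1L)) stop("interval start < 1")
  if (length(start) && any(end < start)) stop("interval end < start")
  ord <- order(protein, start)
  protein <- protein[ord]; start <- start[ord]; end <- end[ord]
  tms <- stats::ave(start, protein, FUN = seq_along)
  # non-overlap within each protein
  for (p in unique(protein)) {
    i <- which(protein == p)
    if (length(i) > 1 && any(start[i][-1] <= end[i][-length(i)]))
      stop("overlapping TMS intervals on ", p)
    if (!is.null(proteins)) {
      len <- nchar(seq_of(proteins, p))
      if (any(end[i] > len))
        stop("TMS interval beyond sequence end on ", p,
             " (length ", len, ")")
    }
  }
  df <- data.frame(protein = protein, tms = as.integer(tms),
                   start = start, end = end,
                   source = rep_len(source, length(protein)),
                   stringsAsFactors = FALSE)
  class(df) <- c("tms_annotation", "data.frame")
  df
}

# Intervals of one protein as a two-column matrix (start, end).
tms_of <- function(topology, accession) {
  t <- topology[topology$protein == accession, , drop = FALSE]
  t <- t[order(t$start), , drop = FALSE]
  cbind(start = t$start, end = t$end)
}

#' Construct a domain hit table
#'
#' Domain (e.g. Pfam) hits on proteins, either read directly from an
#' hmmscan tabular file ([read_domtblout()]) or created by projection from
#' a family member with a direct hit ([project_domain()]). Envelope
#' coordinates are 1-based inclusive.
#'
#' @param protein,domain_acc,clan character vectors.
#' @param env_start,env_end integer envelope coordinates.
#' @param evalue numeric significance.
#' @param origin `"direct"` or `"projected"`.
#' @param projected_from accession of the donor protein for projected hits.
#' @return A data frame of class `domain_hits`.
#' @export
domain_hits <- function(protein, domain_acc, env_start, env_end, evalue,
                        clan = NA_character_, origin = "direct",
                        projected_from = NA_character_) {
  n <- length(protein)
  env_start <- as.integer(env_start); env_end <- as.integer(env_end)
  if (n && any(env_start > env_end)) stop("env_start > env_end")
  origin <- rep_len(origin, n)
  projected_from <- rep_len(as.character(projected_from), n)
  if (any(origin == "projected" & is.na(projected_from)))
    stop("projected hits must record projected_from")
  df <- data.frame(protein = as.character(protein),
                   domain_acc = as.character(domain_acc),
                   clan = rep_len(as.character(clan), n),
                   env_start = env_start, env_end = env_end,
                   evalue = as.numeric(evalue),
                   origin = origin, projected_from = projected_from,
                   stringsAsFactors = FALSE)
  class(df) <- c("domain_hits", "data.frame")
  df
}

#' Run configuration
#'
#' Bundles the scoring system and all pipeline thresholds so that every
#' stage logs and applies one consistent set of parameters.
#'
#' Defaults mirror a standard SSEARCH-style setup: BLOSUM50 with affine
#' gap penalties 10 (open) and 2 (per residue), 1000 composition-preserving
#' shuffles for E-value calibration, Kyte-Doolittle hydropathy averaged
#' over a 19-residue window, and the screening thresholds used throughout
#' the transitivity analysis (candidate E-value < 1e-4 at >= 40% coverage
#' of the shorter sequence, 90% identity redundancy reduction, path
#' E-value < 1e-5 with at least 3 aligned TMSs).
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings).
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param shuffles number of shuffles K for E-value calibration.
#' @param seed integer seed used for all randomized steps.
#' @param scale hydropathy scale name (currently `"kyte-doolittle"`).
#' @param window odd hydropathy averaging window (>= 5).
#' @param tms_peak,tms_min_len,tms_max_len,tms_merge_gap TMS caller knobs:
#'   window-averaged hydropathy threshold, minimal/maximal segment length,
#'   and the maximal loop length merged between adjacent runs.
#' @param screen_evalue,screen_coverage,redundancy_identity homolog
#'   screening thresholds.
#' @param path_evalue,min_tms transitivity-path thresholds.
#' @param repeat_evalue significance threshold for intra-protein repeats.
#' @param projection_evalue,projection_coverage domain projection thresholds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(matrix = "BLOSUM50", gap_open = 10, gap_extend = 2,
                       shuffles = 1000L, seed = 101L,
                       scale = "kyte-doolittle", window = 19L,
                       tms_peak = 1.0, tms_min_len = 15L, tms_max_len = 30L,
                       tms_merge_gap = 4L,
                       screen_evalue = 1e-4, screen_coverage = 0.40,
                       redundancy_identity = 0.90,
                       path_evalue = 1e-5, min_tms = 3L,
                       repeat_evalue = 1e-3,
                       projection_evalue = 1e-5, projection_coverage = 0.40) {
  if (window %% 2L == 0L || window < 5L) stop("window must be odd and >= 5")
  if (shuffles < 1L) stop("shuffles (K) must be >= 1")
  cfg <- list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
              shuffles = as.integer(shuffles), seed = as.integer(seed),
              scale = scale, window = as.integer(window),
              tms_peak = tms_peak, tms_min_len = as.integer(tms_min_len),
              tms_max_len = as.integer(tms_max_len),
              tms_merge_gap = as.integer(tms_merge_gap),
              screen_evalue = screen_evalue, screen_coverage = screen_coverage,
              redundancy_identity = redundancy_identity,
              path_evalue = path_evalue, min_tms = as.integer(min_tms),
              repeat_evalue = repeat_evalue,
              projection_evalue = projection_evalue,
              projection_coverage = projection_coverage)
  class(cfg) <- "run_config"
  tk_log("config: matrix=", matrix, " gaps=", gap_open, "/", gap_extend,
         " K=", shuffles, " seed=", seed)
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("tmskit run_config\n")
  cat("  scoring:   ", x$matrix, " open=", x$gap_open,
      " extend=", x$gap_extend, "\n", sep = "")
  cat("  shuffles K:", x$shuffles, " seed:", x$seed, "\n")
  cat("  hydropathy:", x$scale, "window", x$window, "\n")
  cat("  TMS caller: peak>=", x$tms_peak, " len ", x$tms_min_len, "-",
      x$tms_max_len, " merge-gap ", x$tms_merge_gap, "\n", sep = "")
  cat("  screening: E<", x$screen_evalue, " cov>=", x$screen_coverage,
      " cd-hit ", x$redundancy_identity, "\n", sep = "")
  cat("  path:      E<", x$path_evalue, " >=", x$min_tms, " TMS\n", sep = "")
  invisible(x)
}
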