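#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace into accession and
#' description. Sequences are uppercased; duplicate accessions and gap
#' characters are rejected.
#'
#' @param path FASTA file.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_set(character(), character()))
  }
  headers <- names(set)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(accession = acc, sequence = as.character(set),
              description = desc)
}

#' Write a protein set to FASTA
#'
#' @param proteins a [protein_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- ifelse(nzchar(proteins$description),
                       paste(proteins$accession, proteins$description),
                       proteins$accession)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' All rows must be the same length; gap characters `-` and `.` are
#' normalized to `-`.
#'
#' @param path aligned FASTA file.
#' @return A named character vector of equal-length gapped rows, class
#'   `msa`.
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty MSA: ", path)
  rows <- toupper(chartr(".", "-", as.character(set)))
  names(rows) <- sub("\\s.*$", "", names(set))
  as_msa(rows)
}

# Validate and class an MSA (named character vector of equal-length rows).
as_msa <- function(rows) {
  if (length(unique(nchar(rows))) != 1L)
    stop("MSA rows differ in length")
  class(rows) <- "msa"
  rows
}

#' Read TMS annotations
#'
#' Two dialects are supported. `"hmmtop"` parses the classic one-line
#' output format, whose tail is `<IN|OUT> <n_helices> <pos1> ... <pos2n>`,
#' with positions in 1-based inclusive pairs. `"tsv"` expects three
#' columns `protein start end` (no header; comment lines with `#`
#' skipped).
#'
#' @param path input file.
#' @param dialect `"hmmtop"` or `"tsv"`.
#' @param proteins optional [protein_set()] for bounds validation.
#' @return A [tms_annotation()] with `source = "imported"`.
#' @export
read_topology <- function(path, dialect = c("hmmtop", "tsv"), proteins = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  prot <- character(); st <- integer(); en <- integer()
  if (dialect == "tsv") {
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(f) < 3L)
        stop("line ", i, ": expected 'protein start end'")
      prot <- c(prot, f[1]); st <- c(st, as.integer(f[2]))
      en <- c(en, as.integer(f[3]))
    }
  } else {
    for (i in seq_along(lines)) {
      f <- strsplit(trimws(sub("^>HP:\\s*", "", lines[i])), "\\s+")[[1]]
      loc <- which(f %in% c("IN", "OUT"))
      if (length(loc) == 0L)
        stop("line ", i, ": no IN/OUT localization field; not HMMTOP one-line format")
      loc <- loc[length(loc)]
      acc <- f[2]
      nh <- suppressWarnings(as.integer(f[loc + 1L]))
      if (is.na(nh) || length(f) < loc + 1L + 2L * nh)
        stop("line ", i, ": helix count/positions malformed")
      if (nh > 0L) {
        pos <- as.integer(f[(loc + 2L):(loc + 1L + 2L * nh)])
        prot <- c(prot, rep(acc, nh))
        st <- c(st, pos[seq(1L, 2L * nh, by = 2L)])
        en <- c(en, pos[seq(2L, 2L * nh, by = 2L)])
      }
    }
  }
  tms_annotation(prot, st, en, source = "imported", proteins = proteins)
}

#' Write TMS annotations as TSV
#'
#' @param topology a [tms_annotation()].
#' @param path output file.
#' @param config optional [run_config()] recorded in the commented header.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path, config = NULL) {
  write_tsv_commented(as.data.frame(topology), path, config)
}

#' Read HMMER3 per-domain hits (domtblout)
#'
#' Parses the 22 fixed whitespace-separated columns of `hmmscan
#' --domtblout` output plus the free-text description. One [domain_hits()]
#' row is produced per domain row, using envelope coordinates; `origin` is
#' `"direct"`. Comment lines are skipped.
#'
#' @param path domtblout file.
#' @return A [domain_hits()] table.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) == 0L)
    return(domain_hits(character(), character(), integer(), integer(),
                       numeric()))
  parse_row <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("line ", i, ": expected >= 22 columns in domtblout, got ",
           length(f))
    # domtblout: target name, target acc, tlen, query name, query acc,
    # qlen, full E/score/bias, dom #, dom of, c-E, i-E, score, bias,
    # hmm from/to, ali from/to, env from/to, acc, description...
    list(protein = f[4], domain_acc = if (f[2] == "-") f[1] else f[2],
         env_start = as.integer(f[20]), env_end = as.integer(f[21]),
         evalue = as.numeric(f[13]))
  }
  rows <- lapply(seq_along(lines), parse_row)
  domain_hits(protein = vapply(rows, `[[`, "", "protein"),
              domain_acc = vapply(rows, `[[`, "", "domain_acc"),
              env_start = vapply(rows, `[[`, 0L, "env_start"),
              env_end = vapply(rows, `[[`, 0L, "env_end"),
              evalue = vapply(rows, `[[`, 0, "evalue"))
}

#' Read a family membership table
#'
#' Two tab-separated columns, `accession<TAB>family`; comment lines with
#' `#` are skipped.
#'
#' @param path TSV file.
#' @return A data frame with columns `accession` and `family`.
#' @export
read_family_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("accession", "family"),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$accession))
    stop("duplicate accessions in family table")
  df
}
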