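# Local pairwise alignment with affine gaps, shuffle-calibrated E-values,
# bit scores and greedy redundancy reduction. The dynamic programming is
# delegated to Biostrings::pairwiseAlignment (Smith-Waterman, affine gaps,
# gap of length L costing open + extend * L, matching SSEARCH-style
# penalties); everything around it -- shuffling, Gumbel fitting, scoring
# conventions -- lives here.

# Cache substitution matrices shipped with Biostrings.
.matrix_cache <- new.env(parent = emptyenv())

get_submatrix <- function(name) {
  if (!exists(name, envir = .matrix_cache)) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !exists(name, envir = e))
      stop("unknown substitution matrix: ", name)
    assign(name, get(name, envir = e), envir = .matrix_cache)
  }
  get(name, envir = .matrix_cache)
}

# Non-standard residues are kept in records but scored as X.
sanitize_for_scoring <- function(seq) chartr("BZUO", "XXXX", seq)

# Restore original residues into a gapped aligned string.
restore_residues <- function(aln_str, original, from) {
  chars <- strsplit(aln_str, "")[[1]]
  idx <- which(chars != "-")
  if (length(idx))
    chars[idx] <- strsplit(substr(original, from, from + length(idx) - 1L),
                           "")[[1]]
  paste(chars, collapse = "")
}

#' Extreme-value (Gumbel) constants for a scoring system
#'
#' Published ungapped Gumbel constants are shipped for BLOSUM50 and
#' BLOSUM62; for the package's default gapped system (BLOSUM50, gap open
#' 10, extend 2) constants were calibrated once by maximum-likelihood
#' Gumbel fits to Smith-Waterman scores of shuffled random sequence pairs
#' (see the methods vignette). For any other system, supply a
#' [gumbel_fit()] to [bit_score()] instead.
#'
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend affine gap penalties; `Inf, Inf` selects the
#'   ungapped constants.
#' @return A list with elements `lambda` (nats per score unit) and `K`.
#' @export
matrix_constants <- function(matrix = "BLOSUM50", gap_open = 10, gap_extend = 2) {
  key <- paste(matrix, gap_open, gap_extend, sep = "/")
  table <- list(
    "BLOSUM50/Inf/Inf" = list(lambda = 0.232, K = 0.112),  # ungapped, published
    "BLOSUM62/Inf/Inf" = list(lambda = 0.318, K = 0.134),  # ungapped, published
    "BLOSUM62/11/1"    = list(lambda = 0.267, K = 0.041),  # gapped, published
    "BLOSUM50/10/2"    = list(lambda = 0.174, K = 0.023)   # shuffle-calibrated
  )
  out <- table[[key]]
  if (is.null(out))
    stop("no Gumbel constants for ", key,
         "; supply a gumbel_fit to bit_score()")
  out
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * S - ln K) / ln 2` under the extreme-value constants
#' of the scoring system.
#'
#' @param raw_score raw Smith-Waterman score in matrix units.
#' @param params a list with `lambda` and `K`: either
#'   [matrix_constants()] or a [gumbel_fit()] converted via
#'   [fit_constants()].
#' @return Score in bits.
#' @export
bit_score <- function(raw_score, params) {
  if (is.null(params$lambda) || is.null(params$K))
    stop("params must carry lambda and K (matrix constants or a Gumbel fit)")
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Smith-Waterman local alignment of two sequences
#'
#' Optimal local alignment under affine-gap scoring (a gap of length L
#' costs `gap_open + gap_extend * L`). Identity is the fraction of
#' alignment columns with identical residues; `coverage_shorter` is the
#' alignment length in columns (gaps included) divided by the length of
#' the shorter sequence. If no cell scores positively, an empty alignment
#' with `raw_score = 0` is returned.
#'
#' @param seq_a,seq_b amino-acid sequences (query, subject).
#' @param config a [run_config()].
#' @param query,subject labels recorded in the result.
#' @param evalue if `TRUE`, attach a shuffle-calibrated E-value via
#'   [shuffle_evalue()].
#' @return A list of class `local_alignment`.
#' @seealso [shuffle_evalue()], [bit_score()]
#' @export
smith_waterman <- function(seq_a, seq_b, config = run_config(),
                           query = "query", subject = "subject",
                           evalue = FALSE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  mat <- get_submatrix(config$matrix)
  sa <- sanitize_for_scoring(seq_a); sb <- sanitize_for_scoring(seq_b)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "local",
    substitutionMatrix = mat, gapOpening = config$gap_open,
    gapExtension = config$gap_extend)
  sc <- Biostrings::score(pa)
  consts <- tryCatch(matrix_constants(config$matrix, config$gap_open,
                                      config$gap_extend),
                     error = function(e) NULL)
  empty <- sc <= 0 || Biostrings::nchar(pa) == 0L
  if (empty) {
    aln <- list(query = query, subject = subject,
                q_start = 0L, q_end = 0L, s_start = 0L, s_end = 0L,
                q_aln = "", s_aln = "", raw_score = 0,
                bit_score = if (!is.null(consts)) bit_score(0, consts) else NA_real_,
                identity = 0, coverage_shorter = 0,
                evalue = NA_real_, z_score = NA_real_, shuffles = NA_integer_,
                evalue_flagged = FALSE)
  } else {
    q_aln <- as.character(Biostrings::alignedPattern(pa))
    s_aln <- as.character(Biostrings::alignedSubject(pa))
    qs <- Biostrings::start(Biostrings::pattern(pa))
    ss <- Biostrings::start(Biostrings::subject(pa))
    q_aln <- restore_residues(q_aln, seq_a, qs)
    s_aln <- restore_residues(s_aln, seq_b, ss)
    qc <- strsplit(q_aln, "")[[1]]; sc2 <- strsplit(s_aln, "")[[1]]
    ident <- sum(qc == sc2 & qc != "-") / length(qc)
    aln <- list(query = query, subject = subject,
                q_start = qs, q_end = Biostrings::end(Biostrings::pattern(pa)),
                s_start = ss, s_end = Biostrings::end(Biostrings::subject(pa)),
                q_aln = q_aln, s_aln = s_aln, raw_score = sc,
                bit_score = if (!is.null(consts)) bit_score(sc, consts) else NA_real_,
                identity = ident,
                coverage_shorter = length(qc) / min(nchar(seq_a), nchar(seq_b)),
                evalue = NA_real_, z_score = NA_real_, shuffles = NA_integer_,
                evalue_flagged = FALSE)
  }
  class(aln) <- "local_alignment"
  if (evalue) {
    ev <- shuffle_evalue(seq_a, seq_b, aln$raw_score, config)
    aln$evalue <- ev$evalue; aln$z_score <- ev$z_score
    aln$shuffles <- ev$fit$n_samples; aln$evalue_flagged <- ev$flagged
  }
  aln
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("local_alignment %s[%d-%d] vs %s[%d-%d]\n", x$query, x$q_start,
              x$q_end, x$subject, x$s_start, x$s_end))
  cat(sprintf("  raw %.1f  bits %.1f  identity %.1f%%  coverage %.1f%%\n",
              x$raw_score, x$bit_score, 100 * x$identity,
              100 * x$coverage_shorter))
  if (!is.na(x$evalue))
    cat(sprintf("  E-value %.3g (K=%d shuffles, z=%.1f)%s\n", x$evalue,
                x$shuffles, x$z_score,
                if (isTRUE(x$evalue_flagged)) " [upper bound]" else ""))
  invisible(x)
}

# Two-stage screen: when Gumbel constants are available for the scoring
# system, a raw score whose predicted E-value (K m n e^{-lambda S}) is
# more than `slack` above the threshold cannot plausibly pass, so the
# shuffle calibration can be skipped. Returns FALSE (i.e. "do compute")
# when no constants are shipped.
likely_insignificant <- function(raw_score, m, n, config, threshold,
                                 slack = 1e3) {
  consts <- tryCatch(matrix_constants(config$matrix, config$gap_open,
                                      config$gap_extend),
                     error = function(e) NULL)
  if (is.null(consts)) return(FALSE)
  e_pred <- consts$K * m * n * exp(-consts$lambda * raw_score)
  e_pred > threshold * slack
}

# Vectorized optimal local scores of many patterns against one subject.
score_many <- function(pattern_seqs, subject_seq, config) {
  mat <- get_submatrix(config$matrix)
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sanitize_for_scoring(pattern_seqs)),
    Biostrings::AAString(sanitize_for_scoring(subject_seq)),
    type = "local", substitutionMatrix = mat,
    gapOpening = config$gap_open, gapExtension = config$gap_extend,
    scoreOnly = TRUE)
}

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and scale `beta` of a Gumbel (type-I extreme value)
#' distribution to a sample of optimal alignment scores by maximum
#' likelihood. `lambda = 1/beta` is the scale in the E-value
#' parameterization.
#'
#' @param x numeric sample (shuffled optimal scores).
#' @return A list of class `gumbel_fit` with `mu`, `beta`, `lambda`,
#'   `n_samples`, and `degenerate` (`TRUE` when the sample has zero
#'   spread).
#' @export
gumbel_fit <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples for a Gumbel fit")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    fit <- list(mu = mean(x), beta = NA_real_, lambda = NA_real_,
                n_samples = n, degenerate = TRUE)
    class(fit) <- "gumbel_fit"
    return(fit)
  }
  # Profile likelihood in beta: beta = mean(x) - sum(x w)/sum(w),
  # w = exp(-x/beta); solved by fixed-point-safe root bracketing.
  xc <- x - max(x)  # numerical stability in exp()
  g <- function(beta) {
    w <- exp(-xc / beta)
    beta - mean(x) + sum(x * w) / sum(w)
  }
  beta0 <- s * sqrt(6) / pi  # method-of-moments start
  lo <- beta0 / 50; hi <- beta0 * 50
  # widen until sign change (guards odd samples)
  for (i in 1:10) {
    if (g(lo) * g(hi) < 0) break
    lo <- lo / 4; hi <- hi * 4
  }
  beta <- if (g(lo) * g(hi) < 0) uniroot(g, c(lo, hi))$root else beta0
  # mu = -beta log(mean e^{-x/beta}), shifted by max(x) for stability
  mu <- max(x) - beta * log(mean(exp(-xc / beta)))
  fit <- list(mu = mu, beta = beta, lambda = 1 / beta, n_samples = n,
              degenerate = FALSE)
  class(fit) <- "gumbel_fit"
  fit
}

#' Convert a Gumbel fit to (lambda, K) constants
#'
#' Matches the E-value form `E = K m n exp(-lambda S)` to the fitted tail
#' `P(S >= s) ~ exp(-(s - mu)/beta)` for a search space of `m * n`
#' residues.
#'
#' @param fit a [gumbel_fit()].
#' @param m,n lengths of the two sequences the fit was computed for.
#' @return A list with `lambda` and `K`, usable in [bit_score()].
#' @export
fit_constants <- function(fit, m, n) {
  if (isTRUE(fit$degenerate)) stop("degenerate fit has no constants")
  list(lambda = fit$lambda, K = exp(fit$mu * fit$lambda) / (m * n))
}

# Upper tail P(S >= s) of a fitted Gumbel, numerically safe far out.
gumbel_tail <- function(fit, s) {
  t <- exp(-(s - fit$mu) / fit$beta)
  p <- -expm1(-t)
  pmax(p, 1e-300)
}

#' Shuffle-calibrated alignment E-value
#'
#' Estimates the significance of an observed local-alignment score by
#' aligning the query against `K` composition-preserving shuffles of the
#' subject, fitting a Gumbel distribution to the shuffled optimal scores
#' by maximum likelihood, and reporting `evalue = context_size * P(S >=
#' observed)`. The shuffle set is driven by `config$seed`, so repeated
#' calls are bitwise reproducible. When the observed score exceeds every
#' shuffled score and the score sample is degenerate (zero spread), the
#' conservative upper bound `1/K` is reported and flagged.
#'
#' @param seq_a,seq_b query and subject sequences.
#' @param observed_score raw score whose significance is wanted; computed
#'   via [smith_waterman()] when `NULL`.
#' @param config a [run_config()]; `config$shuffles` is K.
#' @param context_size number of pairwise comparisons in the current
#'   search context (1 for a single pair).
#' @return A list with `evalue`, `z_score`, `fit` (a [gumbel_fit()]) and
#'   `flagged`.
#' @export
shuffle_evalue <- function(seq_a, seq_b, observed_score = NULL,
                           config = run_config(), context_size = 1) {
  K <- config$shuffles
  if (K < 1L) stop("E-value requested with K = 0 shuffles")
  if (is.null(observed_score))
    observed_score <- smith_waterman(seq_a, seq_b, config)$raw_score
  chars <- strsplit(seq_b, "")[[1]]
  shuffled <- with_seed(config$seed, {
    vapply(seq_len(K),
           function(i) paste(sample(chars), collapse = ""), "")
  })
  scores <- score_many(shuffled, seq_a, config)
  scores <- pmax(scores, 0)  # empty local alignment scores as 0
  m <- mean(scores); s <- sd(scores)
  z <- if (is.finite(s) && s > 0) (observed_score - m) / s else NA_real_
  fit <- gumbel_fit(scores)
  if (fit$degenerate) {
    if (observed_score > max(scores)) {
      return(list(evalue = context_size / K, z_score = z, fit = fit,
                  flagged = TRUE))
    }
    return(list(evalue = context_size * mean(scores >= observed_score),
                z_score = z, fit = fit, flagged = TRUE))
  }
  p <- gumbel_tail(fit, observed_score)
  list(evalue = context_size * p, z_score = z, fit = fit, flagged = FALSE)
}

#' Greedy redundancy reduction (CD-HIT style)
#'
#' Longest-first greedy clustering: records are visited by decreasing
#' sequence length; a record joins an existing representative when their
#' local alignment has identity at or above `identity_threshold` over at
#' least `min_coverage` of the shorter sequence, otherwise it becomes a
#' new representative. Representatives are returned in input order.
#'
#' @param records a [protein_set()].
#' @param identity_threshold identity cutoff in (0, 1]; default 0.90.
#' @param config a [run_config()].
#' @param min_coverage minimal aligned fraction of the shorter sequence.
#' @return The representative subset of `records`.
#' @export
reduce_redundancy <- function(records, identity_threshold = 0.90,
                              config = run_config(), min_coverage = 0.80) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) <= 1L) return(records)
  ord <- order(-nchar(records$sequence))
  reps <- integer(0)
  # a qualifying join needs >= min_coverage * L_short aligned columns at
  # >= identity_threshold matches; with d = min diagonal score and worst
  # per-column cost w, the optimal score of such a pair is at least
  # cov * L_short * (t*d - (1-t)*w) -- scores below that bound cannot join
  mat <- get_submatrix(config$matrix)
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")
  d_min <- min(diag(mat[aa20, aa20]))
  w <- max(-min(mat[aa20, aa20]), config$gap_open + config$gap_extend)
  per_col <- identity_threshold * d_min - (1 - identity_threshold) * w
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      l_short <- min(nchar(records$sequence[i]), nchar(records$sequence[r]))
      if (per_col > 0) {
        quick <- score_many(records$sequence[i], records$sequence[r], config)
        if (quick < min_coverage * l_short * per_col) next
      }
      a <- smith_waterman(records$sequence[i], records$sequence[r], config)
      if (a$coverage_shorter >= min_coverage &&
          a$identity >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  out <- records[sort(reps), , drop = FALSE]
  class(out) <- c("protein_set", "data.frame")
  tk_log("reduce_redundancy: ", nrow(records), " -> ", nrow(out),
         " at identity ", identity_threshold)
  out
}

#' Write alignments as TSV
#'
#' One row per alignment: coordinates, raw and bit scores, identity and
#' coverage percentages, E-value, z-score and shuffle count, preceded by a
#' commented header with the configuration.
#'
#' @param alignments a list of `local_alignment` objects.
#' @param path output file.
#' @param config optional [run_config()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, config = NULL) {
  df <- do.call(rbind, lapply(alignments, function(a)
    data.frame(query = a$query, subject = a$subject,
               q_start = a$q_start, q_end = a$q_end,
               s_start = a$s_start, s_end = a$s_end,
               raw = a$raw_score, bits = round(a$bit_score, 2),
               identity_pct = round(100 * a$identity, 1),
               coverage_pct = round(100 * a$coverage_shorter, 1),
               evalue = a$evalue, z = round(a$z_score, 2), K = a$shuffles,
               stringsAsFactors = FALSE)))
  write_tsv_commented(df, path, config)
}
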