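# Hydropathy profiles, TMS prediction, MSA-average curves, MSA trimming
# and per-TMS complexity classification.

# Kyte-Doolittle hydropathy scale.
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2,
               # ambiguity codes: average of the members / neutral for X
               B = -3.5, Z = -3.5, U = 2.5, O = -3.9, X = 0)

hydropathy_scale <- function(name = "kyte-doolittle") {
  if (!identical(tolower(name), "kyte-doolittle"))
    stop("unknown hydropathy scale: ", name)
  .kd_scale
}

#' Per-residue window-averaged hydropathy profile
#'
#' The value at position i is the mean scale value over a centered window
#' of `window` residues; at the sequence ends the window shrinks to what
#' is available, and those positions are flagged as edge-truncated.
#'
#' @param record one row of a [protein_set()], or a list with `accession`
#'   and `sequence`.
#' @param scale hydropathy scale name.
#' @param window odd window width, at most the sequence length.
#' @return A list of class `hydropathy_profile` with `protein`, `values`,
#'   `edge` (logical, window truncated), `scale` and `window`.
#' @export
hydropathy_profile <- function(record, scale = "kyte-doolittle", window = 19L) {
  if (window %% 2L == 0L) stop("window must be odd")
  seqc <- record$sequence
  L <- nchar(seqc)
  if (window > L) stop("window wider than sequence")
  sc <- hydropathy_scale(scale)
  v <- unname(sc[strsplit(seqc, "")[[1]]])
  h <- (window - 1L) %/% 2L
  # cumulative-sum sliding mean with shrinking windows at the ends
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- list(protein = record$accession, values = vals,
              edge = (hi - lo + 1L) < window, scale = scale,
              window = as.integer(window))
  class(out) <- "hydropathy_profile"
  out
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Maximal runs of positions with window-averaged hydropathy at or above
#' `config$tms_peak` are candidate segments. Runs separated by fewer than
#' `tms_merge_gap` residues are merged; runs shorter than `tms_min_len`
#' are discarded; runs longer than `tms_max_len` are split at their
#' interior hydropathy minimum (recursively).
#'
#' @param profile a [hydropathy_profile()].
#' @param config a [run_config()] carrying the caller thresholds.
#' @return A [tms_annotation()] with `source = "predicted"`.
#' @export
predict_tms <- function(profile, config = run_config()) {
  above <- profile$values >= config$tms_peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {
    # merge runs separated by short dips
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap < config$tms_merge_gap)
        merged[nrow(merged), "end"] <- runs[i, "end"]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
    runs <- merged
  }
  # split over-long runs at the interior minimum
  split_run <- function(s, e) {
    if (e - s + 1L <= config$tms_max_len) return(cbind(start = s, end = e))
    interior <- (s + 1L):(e - 1L)
    cut <- interior[which.min(profile$values[interior])]
    rbind(split_run(s, cut - 1L), split_run(cut + 1L, e))
  }
  if (nrow(runs)) {
    runs <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i)
      split_run(runs[i, "start"], runs[i, "end"])))
    runs <- runs[runs[, "end"] - runs[, "start"] + 1L >= config$tms_min_len, ,
                 drop = FALSE]
  }
  tms_annotation(rep(profile$protein, nrow(runs)), runs[, "start"],
                 runs[, "end"], source = "predicted")
}

#' Column profile of a multiple sequence alignment
#'
#' Per-column average hydropathy over non-gap residues, average pairwise
#' similarity (mean substitution-matrix score of all non-gap residue
#' pairs in the column, rescaled to \[0, 1\] by the matrix minimum and
#' maximum), and gap fraction.
#'
#' @param msa an `msa` (named character vector of equal-length rows, see
#'   [read_msa()]).
#' @param scale hydropathy scale name.
#' @param window odd column window over which the hydropathy curve is
#'   smoothed (1 = no smoothing), shrinking at the alignment ends.
#' @param config a [run_config()]; its matrix scores the similarity term.
#' @return A list of class `msa_profile` with a `columns` data frame
#'   (`avg_hydropathy`, `avg_similarity`, `gap_fraction`) and
#'   `n_sequences`.
#' @export
msa_profile <- function(msa, scale = "kyte-doolittle", window = 1L,
                        config = run_config()) {
  if (window %% 2L == 0L) stop("window must be odd")
  if (length(msa) == 0L) stop("empty MSA")
  msa <- as_msa(msa)
  mat <- get_submatrix(config$matrix)
  sc <- hydropathy_scale(scale)
  rows <- do.call(rbind, strsplit(unname(msa), ""))
  ncol_aln <- ncol(rows)
  rng <- range(mat)
  col_stats <- function(j) {
    res <- rows[, j]
    res_ng <- sanitize_for_scoring(paste(res[res != "-"], collapse = ""))
    res_ng <- strsplit(res_ng, "")[[1]]
    k <- length(res_ng)
    gapf <- 1 - k / length(res)
    if (k == 0L) return(c(NA_real_, NA_real_, gapf))
    hyd <- mean(sc[res[res != "-"]])
    # mean over all ordered residue pairs (self-pairs included) so the
    # profile is invariant to duplicating the alignment rows
    sub <- mat[res_ng, res_ng, drop = FALSE]
    sim <- (mean(sub) - rng[1]) / (rng[2] - rng[1])
    c(hyd, sim, gapf)
  }
  st <- vapply(seq_len(ncol_aln), col_stats, numeric(3))
  if (window > 1L) {
    h <- (window - 1L) %/% 2L
    raw <- st[1, ]
    st[1, ] <- vapply(seq_len(ncol_aln), function(j)
      mean(raw[max(1L, j - h):min(ncol_aln, j + h)], na.rm = TRUE),
      numeric(1))
  }
  out <- list(columns = data.frame(avg_hydropathy = st[1, ],
                                   avg_similarity = st[2, ],
                                   gap_fraction = st[3, ]),
              n_sequences = length(msa))
  class(out) <- "msa_profile"
  out
}

#' Remove gap-rich columns from an MSA
#'
#' Keeps only columns whose gap fraction is strictly below
#' `max_gap_fraction` (the "less than 30% gaps" editing rule); row order
#' is preserved. Idempotent.
#'
#' @param msa an `msa`.
#' @param max_gap_fraction columns with gap fraction at or above this are
#'   removed.
#' @return The trimmed `msa`.
#' @export
trim_msa <- function(msa, max_gap_fraction = 0.30) {
  msa <- as_msa(msa)
  rows <- do.call(rbind, strsplit(unname(msa), ""))
  gapf <- colMeans(rows == "-")
  keep <- gapf < max_gap_fraction
  out <- apply(rows[, keep, drop = FALSE], 1, paste, collapse = "")
  names(out) <- names(msa)
  as_msa(out)
}

#' Classify a TMS as simple, twilight or complex
#'
#' A coarse hydrophobicity/complexity classification of a transmembrane
#' segment: segments that are strongly hydrophobic (mean Kyte-Doolittle
#' value of the segment > 2.0) and compositionally biased (Shannon entropy
#' over the 20-letter alphabet < 2.0 bits) are `simple`; segments whose
#' entropy falls in \[2.0, 3.0\] bits or whose mean hydropathy falls in
#' \[1.0, 2.0\] are `twilight`; everything else is `complex`. Simple TMSs
#' are alignment-bias-prone and weaken homology evidence. This is an
#' approximation of hydrophobicity/complexity classifiers used in the
#' field, not a re-implementation of any specific discriminant.
#'
#' @param record protein record (list with `sequence`).
#' @param interval `c(start, end)` residue interval, 1-based inclusive.
#' @param simple_entropy,twilight_entropy entropy thresholds in bits.
#' @param simple_hydropathy,twilight_hydropathy mean-KD thresholds.
#' @return One of `"simple"`, `"twilight"`, `"complex"`.
#' @export
classify_tms <- function(record, interval,
                         simple_entropy = 2.0, twilight_entropy = 3.0,
                         simple_hydropathy = 2.0, twilight_hydropathy = 1.0) {
  L <- nchar(record$sequence)
  if (interval[1] < 1 || interval[2] > L || interval[1] > interval[2])
    stop("interval out of bounds")
  seg <- strsplit(substr(record$sequence, interval[1], interval[2]), "")[[1]]
  sc <- hydropathy_scale("kyte-doolittle")
  hyd <- mean(sc[seg])
  p <- table(seg) / length(seg)
  entropy <- -sum(p * log2(p))
  if (entropy < simple_entropy && hyd > simple_hydropathy) return("simple")
  if ((entropy >= simple_entropy && entropy <= twilight_entropy) ||
      (hyd >= twilight_hydropathy && hyd <= simple_hydropathy))
    return("twilight")
  "complex"
}

#' Plot a hydropathy profile with TMS bars
#'
#' Base-graphics rendering of a hydropathy curve, optionally overlaying
#' TMS intervals as shaded bars and domain hits as horizontal bars. Open a
#' `svg()` or `png()` device around the call to write a file.
#'
#' @param x a [hydropathy_profile()].
#' @param topology optional [tms_annotation()] to overlay.
#' @param domains optional [domain_hits()] to overlay.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @importFrom graphics abline lines rect segments
#' @export
plot.hydropathy_profile <- function(x, topology = NULL, domains = NULL, ...) {
  n <- length(x$values)
  plot(seq_len(n), x$values, type = "n", xlab = "residue",
       ylab = paste0("hydropathy (", x$scale, ", w=", x$window, ")"),
       main = x$protein, ...)
  if (!is.null(topology)) {
    iv <- tms_of(topology, x$protein)
    if (nrow(iv))
      rect(iv[, "start"], par_usr_lo(), iv[, "end"], par_usr_hi(),
           col = grDevices::adjustcolor("orange", 0.35), border = NA)
  }
  if (!is.null(domains)) {
    dh <- domains[domains$protein == x$protein, , drop = FALSE]
    if (nrow(dh))
      segments(dh$env_start, par_usr_hi() * 0.95, dh$env_end,
               par_usr_hi() * 0.95, lwd = 4, col = "steelblue")
  }
  abline(h = 0, col = "grey")
  lines(seq_len(n), x$values, col = "red", lwd = 1.5)
  invisible(x)
}

par_usr_lo <- function() graphics::par("usr")[3]
par_usr_hi <- function() graphics::par("usr")[4]
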