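# Confidence scoring of accepted family-family inferences and export of
# the relationship network.

#' Confidence score of a homology inference
#'
#' `Score = -N * log10(Evalue)`, where N is the number of TMSs in the
#' B-C alignment: more aligned TMSs and smaller E-values give more
#' reliable inferences.
#'
#' @param n_tms number of TMSs in the alignment (>= 1).
#' @param evalue B-C alignment E-value in (0, 1].
#' @return The raw score.
#' @export
confidence_score <- function(n_tms, evalue) {
  if (any(n_tms < 1)) stop("n_tms must be >= 1")
  if (any(evalue <= 0)) stop("evalue must be positive")
  if (any(evalue > 1)) {
    warning("evalue > 1 clamped; score set to 0")
    evalue <- pmin(evalue, 1)
  }
  -n_tms * log10(evalue)
}

#' Normalize scores and assign confidence levels
#'
#' Scores are normalized to 1.0 by the highest-scoring inference of the
#' set; levels follow the bands high (norm >= 0.6), medium (0.6 > norm
#' >= 0.4) and low (norm < 0.4), boundaries inclusive as stated.
#'
#' @param raw_scores numeric vector of raw confidence scores.
#' @return A data frame with `raw`, `norm` and `level`.
#' @export
normalize_and_level <- function(raw_scores) {
  if (length(raw_scores) == 0L || all(raw_scores <= 0))
    stop("need at least one positive raw score")
  norm <- raw_scores / max(raw_scores)
  level <- ifelse(norm >= 0.6, "high", ifelse(norm >= 0.4, "medium", "low"))
  data.frame(raw = raw_scores, norm = norm, level = level,
             stringsAsFactors = FALSE)
}

#' Build the family-relationship network
#'
#' Undirected network over family labels; when several inferences connect
#' the same family pair, the best (highest normalized score) is kept.
#' Node shading value is the degree.
#'
#' @param inferences a `homology_candidates` list (or list of
#'   `homology_inference`) whose elements carry `norm_score` and `level`
#'   -- see [score_candidates()].
#' @return A list of class `family_network` with `nodes` (family,
#'   degree) and `edges` (family_a, family_d, raw, norm, level).
#' @export
build_network <- function(inferences) {
  edges <- data.frame(family_a = character(), family_d = character(),
                      raw = numeric(), norm = numeric(), level = character(),
                      stringsAsFactors = FALSE)
  for (x in inferences) {
    a <- min(x$family_a, x$family_d); d <- max(x$family_a, x$family_d)
    i <- which(edges$family_a == a & edges$family_d == d)
    row <- data.frame(family_a = a, family_d = d, raw = x$raw_score,
                      norm = x$norm_score, level = x$level,
                      stringsAsFactors = FALSE)
    if (length(i) == 0L) edges <- rbind(edges, row)
    else if (isTRUE(row$norm > edges$norm[i])) edges[i, ] <- row
  }
  fams <- sort(unique(c(edges$family_a, edges$family_d)))
  deg <- vapply(fams, function(f)
    sum(edges$family_a == f) + sum(edges$family_d == f), 0L)
  out <- list(nodes = data.frame(family = fams, degree = deg,
                                 stringsAsFactors = FALSE, row.names = NULL),
              edges = edges)
  class(out) <- "family_network"
  out
}

#' Score a candidate set and assign levels
#'
#' Fills `raw_score`, `norm_score` and `level` across a set of
#' inferences; normalization is per set (the run's highest-scoring
#' inference defines 1.0), so normalized scores are not comparable
#' across runs.
#'
#' @param candidates a list of `homology_inference` objects.
#' @return The list with scores and levels filled in.
#' @export
score_candidates <- function(candidates) {
  if (length(candidates) == 0L) return(candidates)
  raw <- vapply(candidates, `[[`, 0, "raw_score")
  nl <- normalize_and_level(raw)
  for (i in seq_along(candidates)) {
    candidates[[i]]$norm_score <- nl$norm[i]
    candidates[[i]]$level <- nl$level[i]
  }
  candidates
}

#' @export
print.family_network <- function(x, ...) {
  cat("family_network:", nrow(x$nodes), "families,", nrow(x$edges),
      "relationships\n")
  if (nrow(x$edges))
    cat(sprintf("  %s -- %s  norm=%.2f  %s\n", x$edges$family_a,
                x$edges$family_d, x$edges$norm, x$edges$level), sep = "")
  invisible(x)
}

#' Export a family network
#'
#' Writes the edge list as TSV and/or the full network as GraphML (via
#' igraph), with degree on nodes and score/level on edges, for rendering
#' in external network tools.
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_commented(network$edges, path)
  } else {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
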