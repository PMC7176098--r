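# Protein clustering from pairwise Smith-Waterman bit scores:
# all-vs-all distance matrix, average-linkage agglomerative nesting with
# the agglomerative coefficient, tree export, and a greedy
# representative picker.

#' Bit-score distance matrix
#'
#' All-vs-all local alignment bit scores `b(i, j)` are converted to
#' dissimilarities `d(i, j) = 1 - b(i, j) / min(b(i, i), b(j, j))`,
#' clamped to \[0, 1\]: identical sequences are at distance 0 and
#' unrelated pairs approach 1. The alternative normalization by the
#' larger self score is available via `normalize = "max_self"`.
#'
#' @param records a [protein_set()] with at least 2 rows.
#' @param config a [run_config()].
#' @param normalize `"min_self"` (default) or `"max_self"`.
#' @return A list of class `distance_matrix` with `labels` and the
#'   symmetric matrix `d` (zero diagonal).
#' @export
bitscore_distance <- function(records, config = run_config(),
                              normalize = c("min_self", "max_self")) {
  normalize <- match.arg(normalize)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records")
  consts <- matrix_constants(config$matrix, config$gap_open, config$gap_extend)
  bits <- function(s) bit_score(s, consts)
  self <- vapply(seq_len(n), function(i)
    bits(smith_waterman(records$sequence[i], records$sequence[i],
                        config)$raw_score), 0)
  if (any(self <= 0))
    stop("non-positive self bit score for: ",
         paste(records$accession[self <= 0], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(records$accession, records$accession))
  for (i in seq_len(n - 1L)) {
    # vectorized: sequence i against all later sequences
    sc <- score_many(records$sequence[(i + 1L):n], records$sequence[i], config)
    b <- bits(pmax(sc, 0))
    ref <- if (normalize == "min_self") pmin(self[i], self[(i + 1L):n])
           else pmax(self[i], self[(i + 1L):n])
    dij <- pmin(pmax(1 - b / ref, 0), 1)
    d[i, (i + 1L):n] <- dij
    d[(i + 1L):n, i] <- dij
  }
  out <- list(labels = records$accession, d = d)
  class(out) <- "distance_matrix"
  out
}

#' Average-linkage agglomerative clustering
#'
#' Agglomerative nesting with average linkage (UPGMA-style update over
#' all inter-cluster pairs), as implemented by `cluster::agnes`. The
#' agglomerative coefficient is the mean over items of `1 - m(i)/M`,
#' where `m(i)` is the dissimilarity at which item i first merges and M
#' is the final merge height; values near 1 indicate strong clustering
#' structure.
#'
#' @param dist a [bitscore_distance()] result, a `dist` object or a
#'   square symmetric matrix.
#' @return A list of class `cluster_tree`: `merges` (data frame `left`,
#'   `right`, `height` in hclust encoding), `labels`,
#'   `agglomerative_coefficient`, `monotone` (FALSE when height
#'   inversions occurred), and `hclust` (the underlying object).
#' @export
agnes_average <- function(dist) {
  if (inherits(dist, "distance_matrix")) d <- as.dist(dist$d)
  else if (inherits(dist, "dist")) d <- dist
  else d <- as.dist(dist)
  if (attr(d, "Size") < 2L) stop("need at least 2 items")
  ag <- cluster::agnes(d, diss = TRUE, method = "average")
  hc <- stats::as.hclust(ag)
  monotone <- !is.unsorted(hc$height)
  if (!monotone)
    warning("non-monotone merge heights (inversions present)")
  out <- list(merges = data.frame(left = hc$merge[, 1],
                                  right = hc$merge[, 2],
                                  height = hc$height),
              labels = hc$labels,
              agglomerative_coefficient = unname(ag$ac),
              monotone = monotone,
              hclust = hc)
  class(out) <- "cluster_tree"
  out
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree over", length(x$labels), "items; AC =",
      round(x$agglomerative_coefficient, 3), "\n")
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param tree a [agnes_average()] result.
#' @param k number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_clusters <- function(tree, k) cutree(tree$hclust, k = k)

#' Export a cluster tree as Newick or Nexus
#'
#' Merge heights are encoded as branch lengths (ultrametric); labels are
#' escaped per format by the ape writers.
#'
#' @param tree a [agnes_average()] result.
#' @param path output file.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
export_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  phy <- ape::as.phylo(tree$hclust)
  if (format == "newick") ape::write.tree(phy, file = path)
  else ape::write.nexus(phy, file = path)
  invisible(path)
}

#' Greedy maximum-diversity representative picker
#'
#' Helper for building representative subsets that maximize among-family
#' divergence while preserving relative family sizes: within each
#' family, picks members greedily by max-min distance to the already
#' selected set.
#'
#' @param dist a [bitscore_distance()] result.
#' @param families named character vector mapping accession to family.
#' @param n_per_family target representative count per family (recycled
#'   or a named vector).
#' @return Character vector of selected accessions.
#' @export
pick_representatives <- function(dist, families, n_per_family = 2L) {
  labs <- dist$labels
  fams <- unique(families[labs])
  if (length(n_per_family) == 1L)
    n_per_family <- stats::setNames(rep(n_per_family, length(fams)), fams)
  sel <- character(0)
  for (f in fams) {
    members <- labs[families[labs] == f]
    want <- min(n_per_family[[f]], length(members))
    # start from the member farthest from everything selected so far
    while (length(intersect(sel, members)) < want) {
      cand <- setdiff(members, sel)
      if (length(sel) == 0L) pick <- cand[1]
      else {
        mind <- vapply(cand, function(a) min(dist$d[a, sel]), 0)
        pick <- cand[which.max(mind)]
      }
      sel <- c(sel, pick)
    }
  }
  sel
}

#' Write a labeled distance matrix as TSV
#'
#' @param dist a [bitscore_distance()] result.
#' @param path output file.
#' @param config optional [run_config()] for the header.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path, config = NULL) {
  df <- data.frame(accession = dist$labels,
                   as.data.frame(dist$d, check.names = FALSE))
  write_tsv_commented(df, path, config)
}
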