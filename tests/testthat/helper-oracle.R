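# Independent exhaustive dynamic-programming oracle for local alignment
# with affine gaps (Gotoh recurrences, no optimizations). A gap of
# length L costs open + extend * L, matching the package's convention.
# Used only to verify raw scores; deliberately written without reference
# to the package's alignment path.
sw_oracle_score <- function(a, b, mat, open, extend) {
  ac <- strsplit(chartr("BZUO", "XXXX", a), "")[[1]]
  bc <- strsplit(chartr("BZUO", "XXXX", b), "")[[1]]
  n <- length(ac); m <- length(bc)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in a (consuming b)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - extend, E[i, j - 1L] - extend)
      F_[i, j] <- max(H[i - 1L, j] - open - extend, F_[i - 1L, j] - extend)
      H[i, j] <- max(0,
                     H[i - 1L, j - 1L] + mat[ac[i - 1L], bc[j - 1L]],
                     E[i, j], F_[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_protein_seq <- function(n, pool = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}
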