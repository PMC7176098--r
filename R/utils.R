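#' @importFrom methods is
#' @importFrom stats median sd uniroot cutree as.dist runif ave setNames
#' @importFrom utils write.table read.table head tail
#' @importFrom graphics plot par
#' @importFrom grDevices adjustcolor
NULL

# Run `expr` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific child seed from a base seed; keeps values < 2^31.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483587L) + 1L
}

tk_log <- function(..., verbose = getOption("tmskit.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[tmskit] ", ...)
}

# Commented TSV header naming tool version and the thresholds in effect,
# so a run is reconstructable from its outputs.
tsv_header <- function(config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("tmskit")),
                  error = function(e) "dev")
  h <- paste0("# tmskit ", ver)
  if (!is.null(config)) {
    h <- c(h, paste0("# matrix=", config$matrix,
                     " gap_open=", config$gap_open,
                     " gap_extend=", config$gap_extend,
                     " shuffles=", config$shuffles,
                     " seed=", config$seed))
  }
  h
}

write_tsv_commented <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header(config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
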