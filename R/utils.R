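# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical undirected edge key: endpoints sorted lexicographically.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Write a file atomically: write to a temporary sibling, then rename.
atomic_write <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop("cannot write to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[!is.finite(x) & !is.na(x)] <- as.character(x[!is.finite(x) & !is.na(x)])
  out
}
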