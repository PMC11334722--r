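# Independent oracles used to validate the implementation.  These
# deliberately use different algorithms from the package: explicit
# permutation-based isomorphism checks, exhaustive subset/partition
# enumeration, and closed-form combinatorics.

# All permutations of 1..k (k <= 4), one per row.
all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(k - 1L)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  unname(out)
}

# Symmetric pattern adjacency matrix of a graphlet descriptor.
pattern_adj <- function(glet) {
  k <- glet$order
  A <- matrix(FALSE, k, k)
  A[glet$edges] <- TRUE
  A | t(A)
}

adj_matrix_of <- function(ix) {
  n <- length(ix$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(ix$nodes, ix$nodes))
  A[cbind(ix$edges$from, ix$edges$to)] <- TRUE
  A[cbind(ix$edges$to, ix$edges$from)] <- TRUE
  A
}

# Brute-force constrained graphlet census: enumerate every node subset of
# the matching order, try every bijection onto the pattern, and accept the
# subset if some bijection reproduces the pattern's edges exactly with the
# intermediate position at a maximum-degree orbit and seed nodes in all
# remaining positions (both nodes seeds for the 2-node graphlet).
oracle_census <- function(ix, seed_ids) {
  A <- adj_matrix_of(ix)
  nodes <- ix$nodes
  is_seed <- nodes %in% seed_ids
  cat_ <- graphlet_catalogue()
  counts <- setNames(integer(length(cat_)), names(cat_))
  for (k in 2:4) {
    if (length(nodes) < k) next
    perms <- all_perms(k)
    glets <- Filter(function(g) g$order == k, cat_)
    subs <- utils::combn(seq_along(nodes), k)
    for (j in seq_len(ncol(subs))) {
      idx <- subs[, j]
      sub_adj <- A[idx, idx, drop = FALSE]
      ne <- sum(sub_adj) / 2L
      for (g in glets) {
        if (sum(pattern_adj(g)) / 2L != ne) next
        pat <- pattern_adj(g)
        ok <- FALSE
        for (r in seq_len(nrow(perms))) {
          pm <- perms[r, ]
          # pm maps pattern position i -> subset slot pm[i]
          if (!identical(pat, unname(sub_adj[pm, pm]))) next
          if (k == 2L) {
            if (all(is_seed[idx[pm]])) { ok <- TRUE; break }
          } else {
            for (q in g$intermediate_orbit) {
              rest <- idx[pm[setdiff(seq_len(k), q)]]
              if (all(is_seed[rest])) { ok <- TRUE; break }
            }
            if (ok) break
          }
        }
        if (ok) counts[g$id] <- counts[g$id] + 1L
      }
    }
  }
  counts
}

# Exact hypergeometric upper tail by explicit combinatorial summation.
oracle_hyper_tail <- function(k, K, M, n) {
  i <- seq(k, min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# Enumerate all set partitions of 1..n via restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxblock) {
    pos <- length(prefix) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      rec(c(prefix, b), max(maxblock, b))
    }
  }
  rec(integer(), 0L)
  out
}

# Newman modularity of a labelled partition of an unweighted interactome.
oracle_modularity <- function(ix, membership) {
  m <- nrow(ix$edges)
  lab <- setNames(membership, ix$nodes)
  q <- 0
  deg <- node_degree(ix)
  for (c_ in unique(membership)) {
    inside <- names(lab)[lab == c_]
    l_c <- sum(ix$edges$from %in% inside & ix$edges$to %in% inside)
    d_c <- sum(deg[inside])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

# Uniform random interactome on n nodes with edge probability p.
random_interactome <- function(n, p = 0.3) {
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 2L)] <- TRUE
  interactome(pairs[1L, keep], pairs[2L, keep],
              stats::runif(sum(keep), 0.2, 1))
}

# Random baseline for planted-pathway recovery: sample `size` edges
# uniformly from the reference and count how many are planted.
random_edge_recovery <- function(ix, truth, size) {
  keys <- graphflux:::edge_key(ix$edges$from, ix$edges$to)
  pick <- sample(keys, size)
  sum(pick %in% truth$true_edges)
}
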