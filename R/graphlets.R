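#' The nine 2-4-node graphlets
#'
#' Returns the catalogue of all connected non-isomorphic undirected graphs
#' on 2 to 4 nodes, the graphlets G0-G8: G0 edge, G1 3-path, G2 triangle,
#' G3 4-path, G4 3-star, G5 4-cycle, G6 triangle with pendant, G7 diamond
#' (4-clique minus one edge), G8 complete 4-clique.  Each entry records the
#' edge pattern on positions `1..order`, the automorphism orbits, and the
#' intermediate orbit: the orbit of maximum degree within the pattern, whose
#' occupant acts as the intermediate node connecting seed nodes.
#'
#' @return a named list of 9 graphlet descriptors, ordered by
#'   (order, edge count, canonical form).  Each descriptor has fields `id`,
#'   `order`, `edges` (2-column index matrix), `degrees`, `orbits` (list of
#'   index vectors) and `intermediate_orbit` (index vector of the
#'   maximum-degree orbit).
#' @examples
#' length(graphlet_catalogue())   # 9
#' @export
graphlet_catalogue <- function() {
  mk <- function(id, order, edges, orbits) {
    edges <- matrix(edges, ncol = 2L, byrow = TRUE)
    degrees <- tabulate(as.vector(edges), nbins = order)
    maxdeg <- max(degrees)
    inter <- unlist(orbits[vapply(orbits, function(o) degrees[o[1L]] == maxdeg,
                                  TRUE)])
    list(id = id, order = order, edges = edges, degrees = degrees,
         orbits = orbits, intermediate_orbit = sort(inter))
  }
  list(
    G0 = mk("G0", 2L, c(1, 2), list(c(1L, 2L))),
    G1 = mk("G1", 3L, c(1, 2, 2, 3), list(c(1L, 3L), 2L)),
    G2 = mk("G2", 3L, c(1, 2, 1, 3, 2, 3), list(c(1L, 2L, 3L))),
    G3 = mk("G3", 4L, c(1, 2, 2, 3, 3, 4), list(c(1L, 4L), c(2L, 3L))),
    G4 = mk("G4", 4L, c(1, 2, 1, 3, 1, 4), list(1L, c(2L, 3L, 4L))),
    G5 = mk("G5", 4L, c(1, 2, 2, 3, 3, 4, 1, 4), list(c(1L, 2L, 3L, 4L))),
    G6 = mk("G6", 4L, c(1, 2, 1, 3, 2, 3, 1, 4), list(1L, c(2L, 3L), 4L)),
    G7 = mk("G7", 4L, c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4),
            list(c(1L, 2L), c(3L, 4L))),
    G8 = mk("G8", 4L, c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4),
            list(c(1L, 2L, 3L, 4L)))
  )
}

graphlet_ids <- function() names(graphlet_catalogue())

# Classify a connected induced subgraph on 2-4 nodes by order, edge count
# and sorted degree sequence (unique for connected graphs of this size).
# Returns the graphlet id or NA for disconnected/unmatched subgraphs.
.classify_key <- c(
  "2|1|11"   = "G0",
  "3|2|112"  = "G1",
  "3|3|222"  = "G2",
  "4|3|1122" = "G3",
  "4|3|1113" = "G4",
  "4|4|2222" = "G5",
  "4|4|1223" = "G6",
  "4|5|2233" = "G7",
  "4|6|3333" = "G8"
)

classify_pattern <- function(order, n_edges, degrees) {
  key <- paste0(order, "|", n_edges, "|",
                paste(sort(degrees), collapse = ""))
  unname(.classify_key[key])
}

# Internal data prepared once per census: integer adjacency structures.
.graph_index <- function(graph) {
  graph <- as_interactome(graph)
  nodes <- graph$nodes
  n <- length(nodes)
  ef <- match(graph$edges$from, nodes)
  et <- match(graph$edges$to, nodes)
  adj <- matrix(FALSE, n, n)
  adj[cbind(ef, et)] <- TRUE
  adj[cbind(et, ef)] <- TRUE
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  list(nodes = nodes, n = n, emat = cbind(ef, et),
       conf = graph$edges$confidence, adj = adj, nbrs = nbrs)
}

# Seed-constrained census over one indexed graph.
#
# A subset of 2-4 nodes matches graphlet g when its induced subgraph is
# isomorphic to g's pattern and some assignment places the intermediate at a
# maximum-degree orbit with every remaining position occupied by a seed.
# Equivalently: at most one subset member is a non-seed, and a lone non-seed
# must attain the maximum induced degree (the intermediate may itself be a
# seed; G0 requires both endpoints to be seeds).  Enumeration is
# seed-anchored: all-seed subsets, plus (k-1)-seed subsets joined with one
# non-seed drawn from the multi-neighborhood, which keeps the census
# tractable on sparse interactomes.  Each subset is counted once per type.
.census_counts <- function(gi, seed_idx, collect = FALSE) {
  adj <- gi$adj
  nbrs <- gi$nbrs
  is_seed <- rep(FALSE, gi$n)
  is_seed[seed_idx] <- TRUE
  counts <- stats::setNames(integer(9L), graphlet_ids())
  store <- if (collect) {
    stats::setNames(vector("list", 9L), graphlet_ids())
  }
  add <- function(id, subset, epairs) {
    counts[[id]] <<- counts[[id]] + 1L
    if (collect) {
      store[[id]][[length(store[[id]]) + 1L]] <<- epairs
    }
  }
  s <- sort(seed_idx)
  ns <- length(s)

  # G0: seed-seed edges
  if (ns >= 2L) {
    both <- is_seed[gi$emat[, 1L]] & is_seed[gi$emat[, 2L]]
    if (collect) {
      for (i in which(both)) add("G0", NULL, gi$emat[i, , drop = FALSE])
    } else {
      counts[["G0"]] <- sum(both)
    }
  }

  induced_edges <- function(subset) {
    k <- length(subset)
    pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    present <- adj[cbind(subset[pr[, 1L]], subset[pr[, 2L]])]
    cbind(subset[pr[present, 1L]], subset[pr[present, 2L]])
  }

  # all-seed triples and quadruples
  if (ns >= 3L) {
    trip <- utils::combn(s, 3L)
    for (j in seq_len(ncol(trip))) {
      subset <- trip[, j]
      ep <- induced_edges(subset)
      deg <- tabulate(match(as.vector(ep), subset), nbins = 3L)
      id <- classify_pattern(3L, nrow(ep), deg)
      if (!is.na(id)) add(id, subset, ep)
    }
  }
  if (ns >= 4L) {
    quad <- utils::combn(s, 4L)
    for (j in seq_len(ncol(quad))) {
      subset <- quad[, j]
      ep <- induced_edges(subset)
      deg <- tabulate(match(as.vector(ep), subset), nbins = 4L)
      id <- classify_pattern(4L, nrow(ep), deg)
      if (!is.na(id)) add(id, subset, ep)
    }
  }

  # (k-1) seeds + one non-seed intermediate candidate.  For order-3
  # patterns the non-seed must have induced degree 2, i.e. be adjacent to
  # both seeds; for order-4 patterns it must attain the maximum induced
  # degree, which is always >= 2, so candidates are non-seeds adjacent to
  # at least two of the chosen seeds.
  if (ns >= 2L) {
    pair <- utils::combn(s, 2L)
    for (j in seq_len(ncol(pair))) {
      a <- pair[1L, j]; b <- pair[2L, j]
      cand <- intersect(nbrs[[a]], nbrs[[b]])
      cand <- cand[!is_seed[cand]]
      if (!length(cand)) next
      id_ab <- if (adj[a, b]) "G2" else "G1"
      for (v in cand) {
        ep <- rbind(c(a, v), c(b, v))
        if (adj[a, b]) ep <- rbind(ep, c(a, b))
        add(id_ab, c(a, b, v), ep)
      }
    }
  }
  if (ns >= 3L) {
    trip <- utils::combn(s, 3L)
    for (j in seq_len(ncol(trip))) {
      t3 <- trip[, j]
      tally <- tabulate(c(nbrs[[t3[1L]]], nbrs[[t3[2L]]], nbrs[[t3[3L]]]),
                        nbins = gi$n)
      cand <- which(tally >= 2L)
      cand <- cand[!is_seed[cand]]
      if (!length(cand)) next
      e12 <- adj[t3[1L], t3[2L]]
      e13 <- adj[t3[1L], t3[3L]]
      e23 <- adj[t3[2L], t3[3L]]
      base_deg <- c(e12 + e13, e12 + e23, e13 + e23)
      n_base <- e12 + e13 + e23
      for (v in cand) {
        link <- adj[t3, v]
        dv <- sum(link)
        deg <- c(base_deg + link, dv)
        id <- classify_pattern(4L, n_base + dv, deg)
        if (is.na(id) || dv < max(deg)) next
        ep <- induced_edges(c(t3, v))
        add(id, c(t3, v), ep)
      }
    }
  }

  if (collect) {
    matches <- lapply(store, function(lst) {
      if (!length(lst)) {
        return(list(nodes = integer(), edges = matrix(integer(), 0L, 2L)))
      }
      em <- do.call(rbind, lst)
      em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
      em <- unique(em)
      list(nodes = sort(unique(as.vector(em))), edges = em)
    })
    list(counts = counts, matches = matches)
  } else {
    list(counts = counts)
  }
}

#' Count seed-constrained occurrences of one graphlet
#'
#' Counts distinct node subsets of the host graph whose induced subgraph is
#' isomorphic to the graphlet's pattern and which admit an assignment
#' placing an intermediate node at a maximum-degree orbit with seed nodes in
#' every remaining position.  The intermediate may itself be a seed; a G0
#' match requires both endpoints to be seeds.  Each subset is counted once
#' per graphlet type even when several valid assignments exist.
#'
#' @param graph an [interactome()].
#' @param seeds a [seed_set()] (or character vector of seed ids).
#' @param graphlet graphlet id `"G0"`..`"G8"`, or `NULL` for all nine.
#' @return for a single graphlet, a list with `count` and `matches` (list
#'   with matched `nodes` and induced `edges` as node-id matrices); for
#'   `NULL`, a named integer vector of all nine counts.
#' @export
count_constrained <- function(graph, seeds, graphlet = NULL) {
  graph <- as_interactome(graph)
  gi <- .graph_index(graph)
  seed_idx <- .seed_indices(gi, seeds)
  res <- .census_counts(gi, seed_idx, collect = TRUE)
  if (is.null(graphlet)) {
    return(res$counts)
  }
  graphlet <- match.arg(graphlet, graphlet_ids())
  m <- res$matches[[graphlet]]
  list(count = unname(res$counts[graphlet]),
       matches = list(nodes = gi$nodes[m$nodes],
                      edges = matrix(gi$nodes[m$edges], ncol = 2L)))
}

.seed_indices <- function(gi, seeds) {
  ids <- if (inherits(seeds, "seed_set")) names(seeds$weights)
         else as.character(seeds)
  idx <- match(ids, gi$nodes)
  sort(idx[!is.na(idx)])
}

#' Degree-preserving permutation of an interactome
#'
#' Randomizes the edge set by attempted double-edge swaps: two edges
#' `(a,b)` and `(c,d)` on four distinct nodes are replaced by `(a,c),(b,d)`
#' or `(a,d),(b,c)` (chosen at random) provided neither new edge already
#' exists.  The degree sequence is preserved exactly.  Each rewired edge
#' inherits the confidence of the edge it displaced, so the confidence
#' multiset is preserved too.  `ceiling(swap_factor * |E|)` swaps are
#' attempted; if none succeeds (e.g. a triangle, where no four distinct
#' nodes exist) an identical copy is returned with a warning.
#'
#' @param graph an [interactome()] with at least 2 edges.
#' @param swap_factor attempted swaps per edge (default 10, a standard
#'   mixing heuristic).
#' @param rng_seed integer seed; the caller's RNG state is untouched.
#' @return a permuted [interactome()].
#' @export
permute_network <- function(graph, swap_factor = 10, rng_seed = 1L) {
  graph <- as_interactome(graph)
  if (nrow(graph$edges) < 2L) {
    stop("permutation needs at least 2 edges", call. = FALSE)
  }
  if (swap_factor <= 0) stop("'swap_factor' must be > 0", call. = FALSE)
  gi <- .graph_index(graph)
  res <- with_rng_seed(rng_seed,
                       .swap_edges(gi$emat, gi$adj,
                                   ceiling(swap_factor * nrow(gi$emat))))
  if (res$accepted == 0L) {
    warning("no legal double-edge swap exists; returning an identical copy",
            call. = FALSE)
  }
  interactome(gi$nodes[res$emat[, 1L]], gi$nodes[res$emat[, 2L]], gi$conf)
}

# Core swap loop on integer structures; confidence travels with the edge
# slot, so edge i keeps its confidence across rewiring.
.swap_edges <- function(emat, adj, attempts) {
  m <- nrow(emat)
  accepted <- 0L
  for (k in seq_len(attempts)) {
    ij <- sample.int(m, 2L)
    a <- emat[ij[1L], 1L]; b <- emat[ij[1L], 2L]
    cc <- emat[ij[2L], 1L]; d <- emat[ij[2L], 2L]
    if (stats::runif(1L) < 0.5) { tmp <- cc; cc <- d; d <- tmp }
    # propose (a,cc) and (b,d)
    if (a == cc || a == d || b == cc || b == d) next
    if (adj[a, cc] || adj[b, d]) next
    adj[a, b] <- FALSE; adj[b, a] <- FALSE
    adj[cc, d] <- FALSE; adj[d, cc] <- FALSE
    adj[a, cc] <- TRUE; adj[cc, a] <- TRUE
    adj[b, d] <- TRUE; adj[d, b] <- TRUE
    emat[ij[1L], ] <- c(a, cc)
    emat[ij[2L], ] <- c(b, d)
    accepted <- accepted + 1L
  }
  list(emat = emat, adj = adj, accepted = accepted)
}

#' Graphlet frequency significance against a permutation null
#'
#' Counts seed-constrained graphlet occurrences in the observed interactome
#' and in `n_permutations` degree-preserving permutations, then compares
#' them with a one-sided z-test: `z = (observed - mean_perm) / sd_perm`
#' (sample standard deviation) and a graphlet is significant when
#' `z > alpha_z` (default 1.65, the paper-conventional one-sided 5% normal
#' cutoff).  When the permutation counts are constant (`sd = 0`) a graphlet
#' is significant only if the observed count strictly exceeds every
#' permuted count.
#'
#' @param graph an [interactome()].
#' @param seeds a [seed_set()].
#' @param n_permutations number of permuted networks (default 100).
#' @param alpha_z one-sided z cutoff (default 1.65).
#' @param swap_factor see [permute_network()].
#' @param rng_seed integer seed driving all permutations.
#' @return object of class `graphlet_census`: list with `table` (data frame
#'   `graphlet`, `observed`, `perm_mean`, `perm_sd`, `z`, `significant`),
#'   `perm_counts` (matrix `n_permutations` x 9), `matches` (per-graphlet
#'   matched node/edge index sets on `graph`) and `n_nodes`.
#' @export
graphlet_significance <- function(graph, seeds, n_permutations = 100L,
                                  alpha_z = 1.65, swap_factor = 10,
                                  rng_seed = 1L) {
  graph <- as_interactome(graph)
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1", call. = FALSE)
  gi <- .graph_index(graph)
  seed_idx <- .seed_indices(gi, seeds)
  if (length(seed_idx) < 2L) {
    stop("need at least 2 seeds present in the graph", call. = FALSE)
  }
  obs <- .census_counts(gi, seed_idx, collect = TRUE)
  attempts <- ceiling(swap_factor * nrow(gi$emat))
  perm_counts <- with_rng_seed(rng_seed, {
    out <- matrix(0L, n_permutations, 9L,
                  dimnames = list(NULL, graphlet_ids()))
    for (i in seq_len(n_permutations)) {
      sw <- .swap_edges(gi$emat, gi$adj, attempts)
      pgi <- list(n = gi$n, emat = sw$emat, adj = sw$adj,
                  nbrs = lapply(seq_len(gi$n), function(v) which(sw$adj[v, ])))
      out[i, ] <- .census_counts(pgi, seed_idx)$counts
    }
    out
  })
  pm <- colMeans(perm_counts)
  psd <- apply(perm_counts, 2L, stats::sd)        # sample (n-1) sd
  z <- ifelse(psd > 0, (obs$counts - pm) / psd, NA_real_)
  sig <- ifelse(psd > 0, !is.na(z) & z > alpha_z,
                obs$counts > apply(perm_counts, 2L, max))
  structure(list(
    table = data.frame(graphlet = graphlet_ids(),
                       observed = as.integer(obs$counts),
                       perm_mean = pm, perm_sd = psd, z = z,
                       significant = as.logical(sig),
                       stringsAsFactors = FALSE),
    perm_counts = perm_counts,
    matches = obs$matches,
    nodes = gi$nodes,
    params = list(n_permutations = n_permutations, alpha_z = alpha_z,
                  swap_factor = swap_factor, rng_seed = rng_seed)
  ), class = "graphlet_census")
}

#' @export
print.graphlet_census <- function(x, ...) {
  cat("graphlet census (", x$params$n_permutations, " permutations, z > ",
      x$params$alpha_z, "):\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4L)
  invisible(x)
}

#' Write a graphlet census report
#' @param census a `graphlet_census`.
#' @param path output TSV path.
#' @export
write_census <- function(census, path) {
  tb <- census$table
  lines <- c("#graphlet\tobserved\tperm_mean\tperm_sd\tz\tsignificant",
             paste(tb$graphlet, tb$observed, fmt_num(tb$perm_mean),
                   fmt_num(tb$perm_sd), fmt_num(tb$z),
                   tolower(tb$significant), sep = "\t"))
  atomic_write(lines, path)
}

#' Build the graphlet-guided network (GGN)
#'
#' The GGN is the union, over all significantly frequent graphlets, of the
#' matched nodes and their induced edges; it is a subgraph of the reference
#' interactome with identical confidences, the "topologically most
#' important" seed-covering core on which edge selection operates.  If no
#' graphlet is significant an empty GGN is returned with a warning.
#'
#' @param graph the [interactome()] the census was computed on.
#' @param seeds the [seed_set()] used for the census.
#' @param census a [graphlet_significance()] result.
#' @return object of class `ggn`: list with `network` (an interactome),
#'   `significant` (graphlet ids) and `census`.
#' @export
build_ggn <- function(graph, seeds, census) {
  graph <- as_interactome(graph)
  if (!inherits(census, "graphlet_census")) {
    stop("'census' must come from graphlet_significance()", call. = FALSE)
  }
  if (!identical(census$nodes, graph$nodes)) {
    stop("census was computed on a different graph", call. = FALSE)
  }
  sig <- census$table$graphlet[census$table$significant]
  if (!length(sig)) {
    warning("no graphlet is significant; GGN is empty", call. = FALSE)
    net <- interactome(character(), character())
  } else {
    em <- do.call(rbind, lapply(census$matches[sig], `[[`, "edges"))
    net <- restrict_interactome(graph, graph$nodes[em[, 1L]],
                                graph$nodes[em[, 2L]])
  }
  structure(list(network = net, significant = sig, census = census),
            class = "ggn")
}

#' @export
print.ggn <- function(x, ...) {
  cat("graphlet-guided network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges (significant: ",
      paste(x$significant, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
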