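#' Generate a synthetic scale-free interactome
#'
#' Preferential-attachment (Barabasi-Albert) graph emulating the degree
#' structure of real reference interactomes: a power-law degree
#' distribution with a small number of hubs.  Edge confidences are sampled
#' from the chosen distribution over `(0, 1]`: `"uniform"` spreads evidence
#' strength evenly, `"beta"` (Beta(5, 2)) skews toward high-confidence
#' edges the way curated interactomes do.  Output is deterministic per
#' `rng_seed`.
#'
#' @param n_nodes number of nodes.
#' @param attachment edges added per incoming node (default 2).
#' @param confidence_dist `"uniform"` or `"beta"`.
#' @param rng_seed integer seed.
#' @return an [interactome()] with nodes named `n0001`, `n0002`, ...
#' @export
generate_interactome <- function(n_nodes, attachment = 2L,
                                 confidence_dist = c("uniform", "beta"),
                                 rng_seed = 1L) {
  confidence_dist <- match.arg(confidence_dist)
  if (n_nodes <= attachment || attachment < 1L) {
    stop("need n_nodes > attachment >= 1", call. = FALSE)
  }
  with_rng_seed(rng_seed, {
    g <- igraph::sample_pa(n_nodes, power = 1, m = attachment,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    m <- nrow(el)
    conf <- switch(confidence_dist,
                   uniform = stats::runif(m),
                   beta = stats::rbeta(m, 5, 2))
    conf[conf <= 0] <- 1e-6
    conf[conf > 1] <- 1
    width <- max(4L, nchar(as.character(n_nodes)))
    ids <- sprintf(paste0("n%0", width, "d"), seq_len(n_nodes))
    interactome(ids[el[, 1L]], ids[el[, 2L]], conf)
  })
}

#' Plant a recoverable pathway in an interactome
#'
#' Builds a benchmark instance: a connected induced subgraph of the
#' requested size is grown by random BFS expansion and declared the true
#' pathway; its internal edge confidences are boosted toward 1 (mixing
#' weight `boost`), creating a recoverable but non-trivial signal; a stated
#' fraction of pathway nodes becomes the seed set; and annotation gene sets
#' are built with one term for the planted pathway plus degree- and
#' size-matched decoy terms drawn from non-pathway nodes (so enrichment
#' tests stay honest).
#'
#' @param interactome an [interactome()], e.g. from
#'   [generate_interactome()].
#' @param pathway_size number of pathway nodes (must not exceed the graph).
#' @param seed_fraction fraction of pathway nodes revealed as seeds, in
#'   `(0, 1]`.
#' @param boost confidence boost weight in `[0, 1)`:
#'   `c' = c + boost * (1 - c)` on pathway-internal edges (default 0.5).
#' @param n_decoys number of decoy annotation terms (default 5).
#' @param rng_seed integer seed.
#' @return object of class `benchmark_instance`: list with `interactome`
#'   (boosted), `truth` (a [gold_standard()]), `seeds` (a [seed_set()]),
#'   `annotations` (an [annotation_collection()]), `rng_seed` and `params`.
#' @export
plant_pathway <- function(interactome, pathway_size, seed_fraction = 0.4,
                          boost = 0.5, n_decoys = 5L, rng_seed = 1L) {
  interactome <- as_interactome(interactome)
  n <- length(interactome$nodes)
  if (pathway_size > n) {
    stop("pathway_size exceeds the number of nodes", call. = FALSE)
  }
  if (pathway_size < 2L) stop("pathway_size must be >= 2", call. = FALSE)
  if (seed_fraction <= 0 || seed_fraction > 1) {
    stop("'seed_fraction' must lie in (0, 1]", call. = FALSE)
  }
  if (boost < 0 || boost >= 1) stop("'boost' must lie in [0, 1)",
                                    call. = FALSE)
  gi <- .graph_index(interactome)
  with_rng_seed(rng_seed, {
    # random BFS growth of a connected induced subgraph
    start <- sample.int(gi$n, 1L)
    members <- start
    in_set <- rep(FALSE, gi$n)
    in_set[start] <- TRUE
    frontier <- setdiff(gi$nbrs[[start]], members)
    while (length(members) < pathway_size) {
      if (!length(frontier)) {
        stop("no connected subgraph of the requested size reachable from ",
             "the start node", call. = FALSE)
      }
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      in_set[nxt] <- TRUE
      frontier <- union(frontier[frontier != nxt],
                        gi$nbrs[[nxt]][!in_set[gi$nbrs[[nxt]]]])
    }
    pathway <- sort(gi$nodes[members])

    # boost internal confidences toward 1
    e <- interactome$edges
    internal <- e$from %in% pathway & e$to %in% pathway
    e$confidence[internal] <- e$confidence[internal] +
      boost * (1 - e$confidence[internal])
    boosted <- interactome(e$from, e$to, e$confidence)

    seeds_ids <- sort(sample(pathway, ceiling(seed_fraction * pathway_size)))
    seeds <- seed_set(seeds_ids, interactome = boosted)

    truth <- gold_standard(
      true_nodes = pathway,
      true_edges = e[internal, c("from", "to"), drop = FALSE],
      universe_nodes = boosted$nodes,
      universe_edges = boosted$edges[, c("from", "to"), drop = FALSE]
    )

    # decoy terms: size-matched, degree-matched draws from non-pathway nodes
    deg <- node_degree(boosted)
    outside <- setdiff(boosted$nodes, pathway)
    target_deg <- sort(unname(deg[pathway]))
    sets <- list(PLANTED_PATHWAY = pathway)
    descs <- c(PLANTED_PATHWAY = "planted pathway (ground truth)")
    for (d in seq_len(n_decoys)) {
      pool <- outside
      pick <- character(length(target_deg))
      for (i in seq_along(target_deg)) {
        # choose randomly among the 5 closest-degree remaining candidates
        gap <- abs(deg[pool] - target_deg[i])
        cand <- pool[order(gap, pool)][seq_len(min(5L, length(pool)))]
        pick[i] <- cand[sample.int(length(cand), 1L)]
        pool <- pool[pool != pick[i]]
      }
      term <- sprintf("DECOY_%02d", d)
      sets[[term]] <- sort(pick)
      descs[term] <- "degree-matched decoy set"
    }
    annotations <- annotation_collection(sets, descs,
                                         universe = boosted$nodes)

    structure(list(interactome = boosted, truth = truth, seeds = seeds,
                   annotations = annotations, rng_seed = rng_seed,
                   params = list(pathway_size = pathway_size,
                                 seed_fraction = seed_fraction,
                                 boost = boost, n_decoys = n_decoys)),
              class = "benchmark_instance")
  })
}

#' One-call benchmark instance generator
#'
#' Convenience wrapper: [generate_interactome()] followed by
#' [plant_pathway()] under a single seed.  Defaults reflect a desk-scale
#' benchmark: a 500-node scale-free interactome with a planted 25-node
#' pathway of which 40% of the nodes are revealed as seeds.
#'
#' @inheritParams generate_interactome
#' @inheritParams plant_pathway
#' @return a `benchmark_instance`.
#' @export
generate_benchmark <- function(n_nodes = 500L, attachment = 2L,
                               confidence_dist = c("uniform", "beta"),
                               pathway_size = 25L, seed_fraction = 0.4,
                               boost = 0.5, n_decoys = 5L, rng_seed = 1L) {
  ix <- generate_interactome(n_nodes, attachment,
                             match.arg(confidence_dist), rng_seed)
  inst <- plant_pathway(ix, pathway_size, seed_fraction, boost, n_decoys,
                        rng_seed = rng_seed + 1L)
  inst$params <- c(list(n_nodes = n_nodes, attachment = attachment),
                   inst$params)
  inst$rng_seed <- rng_seed
  inst
}

#' @export
print.benchmark_instance <- function(x, ...) {
  cat("benchmark instance: ", length(x$interactome$nodes), "-node ",
      "interactome, ", length(x$truth$true_nodes), "-node planted pathway, ",
      length(x$seeds$weights), " seeds\n", sep = "")
  invisible(x)
}

#' Write a benchmark instance to a directory
#'
#' Emits `interactome.tsv`, `seeds.tsv`, `truth_nodes.txt`,
#' `truth_edges.tsv`, `sets.gmt` and `params.json` — everything needed to
#' run inference and evaluation from files.
#'
#' @param instance a `benchmark_instance`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(instance, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- instance$interactome$edges
  atomic_write(c("#node_a\tnode_b\tconfidence",
                 paste(e$from, e$to, fmt_num(e$confidence), sep = "\t")),
               file.path(dir, "interactome.tsv"))
  w <- instance$seeds$weights
  atomic_write(c("#node\tweight", paste(names(w), fmt_num(w), sep = "\t")),
               file.path(dir, "seeds.tsv"))
  atomic_write(instance$truth$true_nodes, file.path(dir, "truth_nodes.txt"))
  te <- do.call(rbind, strsplit(instance$truth$true_edges, "\r", fixed = TRUE))
  atomic_write(c("#node_a\tnode_b", paste(te[, 1L], te[, 2L], sep = "\t")),
               file.path(dir, "truth_edges.tsv"))
  write_gmt(instance$annotations, file.path(dir, "sets.gmt"))
  atomic_write(jsonlite::toJSON(c(instance$params,
                                  list(rng_seed = instance$rng_seed)),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "params.json"))
  invisible(dir)
}
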