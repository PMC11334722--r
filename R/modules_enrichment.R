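#' Partition a network into modules with Louvain community detection
#'
#' Modularity-maximizing Louvain partition of the (undirected, topological)
#' network; modules are the functional subunits tested downstream for
#' annotation over-representation.  The partition is deterministic for a
#' fixed `rng_seed`, singleton components become singleton modules, and
#' module ids are renumbered by decreasing module size (ties by first node
#' id) so labels are stable across platforms.
#'
#' @param network a `context_network`, `ggn` or [interactome()]; must be
#'   non-empty.
#' @param resolution Louvain resolution parameter (default 1.0; larger
#'   values yield more, smaller modules).
#' @param rng_seed integer seed for the Louvain heuristic.
#' @param weighted use edge confidences as weights (default `FALSE`:
#'   topology only).
#' @return object of class `module_partition`: data frame with columns
#'   `node`, `module`; resolution and seed are kept as attributes.
#' @export
detect_modules <- function(network, resolution = 1.0, rng_seed = 1L,
                           weighted = FALSE) {
  x <- as_interactome(network)
  if (length(x$nodes) == 0L) {
    stop("cannot partition an empty network", call. = FALSE)
  }
  g <- as_igraph(x)
  w <- if (weighted) igraph::E(g)$confidence else NA
  cl <- with_rng_seed(rng_seed,
                      igraph::cluster_louvain(g, weights = w,
                                              resolution = resolution))
  memb <- igraph::membership(cl)
  out <- data.frame(node = names(memb), module = as.integer(memb),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  # stable relabeling: modules numbered by decreasing size, ties by first node
  sizes <- table(out$module)
  first <- tapply(out$node, out$module, min)
  o <- order(-as.integer(sizes), first)
  relabel <- stats::setNames(seq_along(o), names(sizes)[o])
  out$module <- as.integer(relabel[as.character(out$module)])
  rownames(out) <- NULL
  structure(out, resolution = resolution, rng_seed = rng_seed,
            class = c("module_partition", "data.frame"))
}

#' Hypergeometric over-representation of annotation terms in modules
#'
#' For each (module, term) pair with universe size `M`, term size `K`,
#' module size `n` and overlap `k`, computes the exact upper tail
#' `P[X >= k]` for `X ~ Hypergeometric(M, K, n)` and applies a
#' Benjamini-Hochberg adjustment across all pairs; a pair is significant
#' when `adjusted_p < fdr_alpha`.
#'
#' The default universe (`"annotated"`) is the set of background nodes
#' appearing in at least one annotation set: unannotated nodes can never
#' contribute to the overlap and would otherwise inflate `M`.  Use
#' `"interactome"` to test against all background nodes.
#'
#' @param partition a [detect_modules()] result.
#' @param annotations an [annotation_collection()] (e.g. from
#'   [read_gmt()]).
#' @param universe `"annotated"` (default) or `"interactome"`.
#' @param fdr_alpha significance threshold on adjusted p-values
#'   (default 0.05).
#' @param background character vector of background nodes (e.g. reference
#'   interactome nodes); defaults to `annotations$universe`, else to the
#'   union of all annotation sets.
#' @return object of class `enrichment_result`: data frame with columns
#'   `module`, `term`, `k`, `n`, `K`, `M`, `p_value`, `adjusted_p`,
#'   `significant`, sorted by adjusted p.
#' @export
enrich_modules <- function(partition, annotations,
                           universe = c("annotated", "interactome"),
                           fdr_alpha = 0.05, background = NULL) {
  universe <- match.arg(universe)
  if (!inherits(annotations, "annotation_collection")) {
    stop("'annotations' must be an annotation_collection", call. = FALSE)
  }
  background <- background %||% annotations$universe %||%
    unique(unlist(annotations$sets, use.names = FALSE))
  annotated <- unique(unlist(annotations$sets, use.names = FALSE))
  U <- if (universe == "annotated") intersect(background, annotated)
       else unique(background)
  if (!length(U) || !length(intersect(annotated, U))) {
    warning("annotation vocabulary is disjoint from the universe",
            call. = FALSE)
    return(.empty_enrichment(fdr_alpha))
  }
  M <- length(U)
  term_sets <- lapply(annotations$sets, intersect, U)
  modules <- split(partition$node, partition$module)
  rows <- list()
  for (m in names(modules)) {
    mod_nodes <- intersect(modules[[m]], U)
    n <- length(mod_nodes)
    for (term in names(term_sets)) {
      K <- length(term_sets[[term]])
      if (K == 0L) next
      k <- length(intersect(mod_nodes, term_sets[[term]]))
      p <- stats::phyper(k - 1L, K, M - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(module = as.integer(m), term = term, k = k, n = n,
                   K = K, M = M, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_enrichment(fdr_alpha))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < fdr_alpha
  out <- out[order(out$adjusted_p, out$p_value, out$module, out$term), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, fdr_alpha = fdr_alpha, universe_mode = universe,
            class = c("enrichment_result", "data.frame"))
}

.empty_enrichment <- function(fdr_alpha) {
  structure(data.frame(module = integer(), term = character(),
                       k = integer(), n = integer(), K = integer(),
                       M = integer(), p_value = numeric(),
                       adjusted_p = numeric(), significant = logical(),
                       stringsAsFactors = FALSE),
            fdr_alpha = fdr_alpha,
            class = c("enrichment_result", "data.frame"))
}

#' Enrichment profile of a network
#'
#' Collapses an enrichment table over a fixed term vocabulary into a
#' per-network vector: in `"binary"` mode an entry is 1 when the term is
#' significant in at least one module; in `"weighted"` mode it is
#' `-log10` of the best (smallest) adjusted p over modules.  Profiles over
#' a shared vocabulary are comparable across networks with
#' [profile_similarity()].
#'
#' @param enrichment an [enrich_modules()] result.
#' @param vocabulary character vector of term ids defining the profile
#'   dimensions (shared across compared networks).
#' @param mode `"binary"` (default) or `"weighted"`.
#' @return named non-negative numeric vector over `vocabulary`.
#' @export
enrichment_profile <- function(enrichment, vocabulary,
                               mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  prof <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  hit <- enrichment$term %in% vocabulary
  e <- enrichment[hit, , drop = FALSE]
  if (nrow(e)) {
    if (mode == "binary") {
      sig_terms <- unique(e$term[e$significant])
      prof[sig_terms] <- 1
    } else {
      best <- tapply(e$adjusted_p, e$term, min)
      prof[names(best)] <- -log10(pmax(best, .Machine$double.xmin))
    }
  }
  prof
}

#' Cosine similarity between enrichment profiles
#'
#' Cosine similarity of two non-negative profiles over an identical
#' vocabulary; lies in `[0, 1]`, with 0 returned when either profile is
#' all-zero.
#'
#' @param a,b named numeric vectors from [enrichment_profile()] with
#'   identical names.
#' @return similarity in `[0, 1]`.
#' @export
profile_similarity <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b))) {
    stop("profiles must share an identical vocabulary", call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Pairwise similarity matrix and average-linkage clustering of contexts
#'
#' Convenience wrappers for comparing many context-specific networks:
#' `profile_similarity_matrix()` computes all pairwise cosine similarities;
#' `cluster_contexts()` cuts an average-linkage hierarchical clustering of
#' the corresponding distances (`1 - similarity`) into `k` groups.  The
#' clustering algorithm is a pragmatic default, not part of the inference
#' method itself.
#'
#' @param profiles named list of profiles over a shared vocabulary.
#' @return a symmetric numeric matrix with unit diagonal.
#' @export
profile_similarity_matrix <- function(profiles) {
  ids <- names(profiles) %||% as.character(seq_along(profiles))
  n <- length(profiles)
  S <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        S[i, j] <- S[j, i] <- profile_similarity(profiles[[i]], profiles[[j]])
      }
    }
  }
  S
}

#' @rdname profile_similarity_matrix
#' @param similarity a matrix from `profile_similarity_matrix()`.
#' @param k number of clusters.
#' @export
cluster_contexts <- function(similarity, k) {
  if (k < 1L || k > nrow(similarity)) {
    stop("'k' must be between 1 and the number of contexts", call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  stats::cutree(hc, k = k)
}

#' Write a module partition / enrichment table / similarity matrix
#' @param partition a `module_partition`.
#' @param path output TSV path.
#' @export
write_modules <- function(partition, path) {
  lines <- c("#node\tmodule", paste(partition$node, partition$module,
                                    sep = "\t"))
  atomic_write(lines, path)
}

#' @rdname write_modules
#' @param enrichment an `enrichment_result`.
#' @export
write_enrichment <- function(enrichment, path) {
  header <- "#module\tterm\tk\tn\tK\tM\tp\tp_adj\tsignificant"
  rows <- if (nrow(enrichment)) {
    paste(enrichment$module, enrichment$term, enrichment$k, enrichment$n,
          enrichment$K, enrichment$M, fmt_num(enrichment$p_value),
          fmt_num(enrichment$adjusted_p), tolower(enrichment$significant),
          sep = "\t")
  } else character()
  atomic_write(c(header, rows), path)
}

#' @rdname write_modules
#' @param similarity a square similarity matrix with dimnames.
#' @export
write_similarity <- function(similarity, path) {
  ids <- rownames(similarity)
  lines <- c(paste(c("#id", ids), collapse = "\t"),
             vapply(seq_along(ids), function(i) {
               paste(c(ids[i], fmt_num(similarity[i, ])), collapse = "\t")
             }, ""))
  atomic_write(lines, path)
}
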