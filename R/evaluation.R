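#' Gold-standard pathway for evaluation
#'
#' Holds the true node/edge sets of a known pathway together with the
#' universe in which negatives live (by default the reference interactome's
#' nodes and edges).  Truth must be contained in the universe.
#'
#' @param true_nodes character vector of pathway nodes.
#' @param true_edges optional 2-column matrix/data frame of pathway edges.
#' @param universe_nodes character vector of all candidate nodes.
#' @param universe_edges optional 2-column matrix/data frame of all
#'   candidate edges.
#' @return object of class `gold_standard`.
#' @export
gold_standard <- function(true_nodes, true_edges = NULL,
                          universe_nodes, universe_edges = NULL) {
  true_nodes <- unique(as.character(true_nodes))
  universe_nodes <- unique(as.character(universe_nodes))
  if (!all(true_nodes %in% universe_nodes)) {
    stop("true nodes must be contained in the universe", call. = FALSE)
  }
  canon <- function(e) {
    if (is.null(e)) return(NULL)
    e <- as.matrix(e)[, 1:2, drop = FALSE]
    unique(edge_key(as.character(e[, 1L]), as.character(e[, 2L])))
  }
  te <- canon(true_edges)
  ue <- canon(universe_edges)
  if (!is.null(te) && !is.null(ue) && !all(te %in% ue)) {
    stop("true edges must be contained in the universe edges", call. = FALSE)
  }
  structure(list(true_nodes = sort(true_nodes),
                 true_edges = te, universe_nodes = sort(universe_nodes),
                 universe_edges = ue),
            class = "gold_standard")
}

# Step-wise average precision: mean of precision@k over the ranks of the
# positives, with unranked universe items appended last (never retrieved
# before ranked ones).  Trapezoid-free, so no optimistic interpolation.
average_precision <- function(scores, positives, universe) {
  pos <- intersect(positives, universe)
  P <- length(pos)
  if (P == 0L) return(NA_real_)
  sc <- stats::setNames(rep(-Inf, length(universe)), universe)
  common <- intersect(names(scores), universe)
  sc[common] <- scores[common]
  ord <- names(sc)[order(-sc, names(sc))]
  is_pos <- ord %in% pos
  prec_at_k <- cumsum(is_pos) / seq_along(is_pos)
  sum(prec_at_k[is_pos]) / P
}

prf <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  precision <- if (length(predicted)) tp / length(predicted) else 0
  recall <- if (length(truth)) tp / length(truth) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate recovery of a gold-standard pathway
#'
#' Scores an inferred network against known truth at two levels: node
#' recovery and edge recovery.  AUPRC is the step-wise area under the
#' precision-recall curve of the full ranked universe (ranked by the given
#' scores, unranked items last); point precision/recall/F1 are computed at
#' the selected network.  The ratio of positives to universe items is
#' reported so sparsity regimes can be compared.
#'
#' @param predicted a `context_network` (or any network object).
#' @param truth a [gold_standard()].
#' @param node_scores named numeric ranking over nodes (e.g. `p` from
#'   [personalized_pagerank()]); optional.
#' @param edge_scores an [compute_edge_flux()] table; edges are ranked by
#'   `min_flux`.  Optional.
#' @return object of class `evaluation_report`: list of node/edge
#'   precision, recall, F1, AUPRC and positives ratios.
#' @export
evaluate_recovery <- function(predicted, truth, node_scores = NULL,
                              edge_scores = NULL) {
  if (!inherits(truth, "gold_standard")) {
    stop("'truth' must be a gold_standard", call. = FALSE)
  }
  if (!length(truth$true_nodes)) stop("empty truth set", call. = FALSE)
  net <- as_interactome(predicted)
  node_stats <- prf(net$nodes, truth$true_nodes)
  node_auprc <- if (!is.null(node_scores)) {
    average_precision(node_scores, truth$true_nodes, truth$universe_nodes)
  } else NA_real_
  edge_stats <- c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  edge_auprc <- NA_real_
  if (!is.null(truth$true_edges)) {
    pred_edges <- edge_key(net$edges$from, net$edges$to)
    edge_stats <- prf(pred_edges, truth$true_edges)
    if (!is.null(edge_scores) && !is.null(truth$universe_edges)) {
      sc <- stats::setNames(edge_scores$min_flux,
                            edge_key(edge_scores$from, edge_scores$to))
      edge_auprc <- average_precision(sc, truth$true_edges,
                                      truth$universe_edges)
    }
  }
  structure(list(
    node_precision = unname(node_stats["precision"]),
    node_recall = unname(node_stats["recall"]),
    node_f1 = unname(node_stats["f1"]),
    node_auprc = node_auprc,
    edge_precision = unname(edge_stats["precision"]),
    edge_recall = unname(edge_stats["recall"]),
    edge_f1 = unname(edge_stats["f1"]),
    edge_auprc = edge_auprc,
    node_positives_ratio = length(truth$true_nodes) /
      length(truth$universe_nodes),
    edge_positives_ratio = if (!is.null(truth$true_edges) &&
                               !is.null(truth$universe_edges)) {
      length(truth$true_edges) / length(truth$universe_edges)
    } else NA_real_
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("node: P=%.3f R=%.3f F1=%.3f AUPRC=%s\n", x$node_precision,
              x$node_recall, x$node_f1, format(x$node_auprc, digits = 3)))
  cat(sprintf("edge: P=%.3f R=%.3f F1=%.3f AUPRC=%s\n", x$edge_precision,
              x$edge_recall, x$edge_f1, format(x$edge_auprc, digits = 3)))
  invisible(x)
}

#' Hub trimming report
#'
#' Hubs are the top degree quantile of the reference interactome (default
#' top 20%, i.e. the `ceiling(0.2 |V|)` highest-degree nodes, ties broken
#' by node id).  For each hub the reduction ratio
#' `RR = 1 - deg_trimmed / deg_reference` measures the fraction of its
#' interactions removed by trimming; a hub absent from the trimmed network
#' has `RR = 1`.
#'
#' @param reference the reference [interactome()].
#' @param trimmed a `ggn`, `context_network` or interactome contained in
#'   the reference.
#' @param quantile top degree fraction defining hubs (default 0.2).
#' @return object of class `hub_report`: list with `hubs`,
#'   `reduction_ratio` (named, in `[0,1]`), `n_removed` (hubs entirely
#'   absent from the trimmed network) and `mean_reduction`.
#' @export
hub_reduction <- function(reference, trimmed, quantile = 0.2) {
  reference <- as_interactome(reference)
  if (quantile <= 0 || quantile > 1) {
    stop("'quantile' must lie in (0, 1]", call. = FALSE)
  }
  deg_ref <- node_degree(reference)
  n_hubs <- ceiling(quantile * length(reference$nodes))
  ord <- order(-deg_ref, names(deg_ref))
  hubs <- names(deg_ref)[ord][seq_len(n_hubs)]
  deg_trim <- node_degree(trimmed, nodes = hubs)
  rr <- 1 - deg_trim / deg_ref[hubs]
  structure(list(hubs = hubs,
                 reduction_ratio = rr,
                 n_removed = sum(deg_trim == 0L),
                 mean_reduction = mean(rr)),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat("hubs:", length(x$hubs), "| removed entirely:", x$n_removed,
      sprintf("| mean reduction ratio: %.3f\n", x$mean_reduction))
  invisible(x)
}

#' Power-law fit of a degree distribution
#'
#' Least-squares line on `log10(degree)` versus `log10(frequency)` over
#' degrees with non-zero frequency.  The degree exponent is
#' `gamma = -slope`; `r_squared` is the coefficient of determination of the
#' log-log fit.  A scale-free network has an approximately linear log-log
#' degree histogram, so a large `r_squared` with `gamma` around 2-3
#' indicates scale-free structure.
#'
#' @param x a network object, or a data frame with columns `degree` and
#'   `count` (a pre-tabulated degree histogram).
#' @return object of class `powerlaw_fit`: list with `gamma`, `r_squared`,
#'   `n_points` and the underlying `lm` fit.
#' @export
fit_degree_powerlaw <- function(x) {
  if (is.data.frame(x)) {
    hist_df <- x[, c("degree", "count")]
  } else {
    d <- node_degree(as_interactome(x))
    d <- d[d > 0L]
    tb <- table(d)
    hist_df <- data.frame(degree = as.numeric(names(tb)),
                          count = as.numeric(tb))
  }
  hist_df <- hist_df[hist_df$count > 0 & hist_df$degree > 0, , drop = FALSE]
  if (length(unique(hist_df$degree)) < 3L) {
    stop("power-law fit needs at least 3 distinct degrees", call. = FALSE)
  }
  fit <- stats::lm(log10(count) ~ log10(degree), data = hist_df)
  structure(list(gamma = -unname(stats::coef(fit)[2L]),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(hist_df), fit = fit),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit: gamma = %.3f, R^2 = %.3f (%d degree bins)\n",
              x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' Cross-validated seed recovery
#'
#' Splits the seeds into `folds` folds; for each fold the held-out seeds
#' are masked from the seed set, the network is inferred from the remaining
#' seeds, and recovery of the masked seeds among the inferred nodes is
#' scored.  This mirrors driver-gene style evaluations where part of the
#' truth is hidden from the input.
#'
#' @param graph the reference [interactome()].
#' @param seeds a [seed_set()] with at least `folds` seeds.
#' @param folds number of folds (default 5).
#' @param rng_seed seed for the fold split and inference.
#' @param ... further arguments passed to [infer()].
#' @return data frame with one row per fold: `fold`, `n_held`,
#'   `n_recovered`, `recall`.
#' @export
cross_validate_seeds <- function(graph, seeds, folds = 5L, rng_seed = 1L,
                                 ...) {
  ids <- names(seeds$weights)
  if (length(ids) < folds) {
    stop("need at least as many seeds as folds", call. = FALSE)
  }
  assignment <- with_rng_seed(rng_seed,
                              sample(rep_len(seq_len(folds), length(ids))))
  rows <- lapply(seq_len(folds), function(f) {
    held <- ids[assignment == f]
    kept <- ids[assignment != f]
    fit <- infer(graph, seed_set(kept, seeds$weights[kept]),
                 rng_seed = rng_seed, ...)
    rec <- intersect(held, fit$network$network$nodes)
    data.frame(fold = f, n_held = length(held), n_recovered = length(rec),
               recall = if (length(held)) length(rec) / length(held) else NA)
  })
  do.call(rbind, rows)
}
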