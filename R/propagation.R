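#' Personalized PageRank over an interactome
#'
#' Iterates the random-walk-with-teleport fixed point
#' \deqn{p_{t+1} = (1-\lambda)\,\pi + \lambda\, W p_t}
#' where `W` is the degree-normalized adjacency operator
#' (`W[y,x] = 1/deg(x)` for every edge x-y) and \eqn{\pi} is the teleport
#' distribution: seed weights normalized to sum 1 (`teleport = "seeds"`,
#' the personalized form in which omic hits inject probability mass) or
#' uniform `1/N` (`teleport = "uniform"`, plain PageRank).  Mass sitting on
#' degree-0 nodes is redistributed to \eqn{\pi} each step, so the result
#' remains a probability distribution.  Iteration stops when the L1 change
#' drops below `tolerance` or after `max_iterations` sweeps (then flagged
#' not converged, with a warning).
#'
#' @param graph an [interactome()].
#' @param seeds a [seed_set()]; required for `teleport = "seeds"`.
#' @param damping damping factor \eqn{\lambda} in (0,1); default 0.85, the
#'   conventional PageRank value.
#' @param tolerance L1 convergence threshold (default 1e-8).
#' @param max_iterations iteration cap (default 1000).
#' @param teleport `"seeds"` (personalized, default) or `"uniform"`.
#' @return object of class `propagation_result`: list with `p` (named
#'   stationary probabilities summing to 1), `iterations`, `converged` and
#'   the configuration used.
#' @examples
#' ix <- interactome(c("u"), c("v"))
#' s <- seed_set("u", interactome = ix)
#' round(personalized_pagerank(ix, s)$p, 5)
#' @export
personalized_pagerank <- function(graph, seeds = NULL, damping = 0.85,
                                  tolerance = 1e-8, max_iterations = 1000L,
                                  teleport = c("seeds", "uniform")) {
  teleport <- match.arg(teleport)
  graph <- as_interactome(graph)
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L) stop("cannot propagate over an empty graph", call. = FALSE)
  if (damping <= 0 || damping >= 1) {
    stop("'damping' must lie in (0, 1)", call. = FALSE)
  }
  if (teleport == "seeds") {
    if (is.null(seeds)) stop("seed teleport requires a seed set", call. = FALSE)
    w <- seeds$weights[names(seeds$weights) %in% nodes]
    if (!length(w)) stop("no seed is present in the graph", call. = FALSE)
    pi_vec <- numeric(n)
    pi_vec[match(names(w), nodes)] <- w / sum(w)
  } else {
    pi_vec <- rep(1 / n, n)
  }
  deg <- node_degree(graph)
  ef <- match(graph$edges$from, nodes)
  et <- match(graph$edges$to, nodes)
  # W[y, x] = 1/deg(x): column-stochastic over non-dangling columns
  W <- Matrix::sparseMatrix(i = c(et, ef), j = c(ef, et),
                            x = 1 / deg[c(ef, et)], dims = c(n, n))
  dangling <- which(deg == 0L)
  p <- pi_vec
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    spread <- as.numeric(W %*% p)
    if (length(dangling)) {
      spread <- spread + sum(p[dangling]) * pi_vec
    }
    p_new <- (1 - damping) * pi_vec + damping * spread
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("PageRank did not converge in ", max_iterations, " iterations",
            call. = FALSE)
  }
  structure(list(p = stats::setNames(p, nodes), iterations = iter,
                 converged = converged,
                 config = list(damping = damping, tolerance = tolerance,
                               max_iterations = max_iterations,
                               teleport = teleport)),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("propagation over ", length(x$p), " nodes: ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Bidirectional edge-flux scores
#'
#' For each edge `e = {u, t}` of the reference graph the directional fluxes
#' \deqn{f_{u \to t} = p(u)\, c(e) / deg(u), \qquad
#'       f_{t \to u} = p(t)\, c(e) / deg(t)}
#' combine the propagation probability, the edge confidence, and a degree
#' normalization that penalizes hubs.  Degrees are taken in the reference
#' graph.  The edge score is the negative logarithm of the smaller flux,
#' `f(e) = -log(min_flux)`; edges whose minimum flux is 0 (an endpoint with
#' zero propagation mass) receive an infinite score and are excluded from
#' selection.
#'
#' @param graph the reference [interactome()].
#' @param propagation a [personalized_pagerank()] result covering all nodes
#'   of `graph`.
#' @param log_base `"10"` (default) or `"e"`; affects `score` by a constant
#'   factor only, never the ranking.
#' @return an `edge_score_table`: data frame with columns `from`, `to`,
#'   `confidence`, `flux_forward`, `flux_backward`, `min_flux`, `score`;
#'   the log base is kept in `attr(, "log_base")`.
#' @export
compute_edge_flux <- function(graph, propagation, log_base = c("10", "e")) {
  log_base <- match.arg(log_base)
  graph <- as_interactome(graph)
  p <- propagation$p
  if (!all(graph$nodes %in% names(p))) {
    stop("propagation result does not cover all graph nodes", call. = FALSE)
  }
  e <- graph$edges
  check_confidence(e$confidence)
  deg <- node_degree(graph)
  fw <- p[e$from] * e$confidence / deg[e$from]
  bw <- p[e$to] * e$confidence / deg[e$to]
  minf <- pmin(fw, bw)
  lb <- if (log_base == "10") log(10) else 1
  score <- ifelse(minf > 0, -log(minf) / lb, Inf)
  out <- data.frame(from = e$from, to = e$to, confidence = e$confidence,
                    flux_forward = as.numeric(fw),
                    flux_backward = as.numeric(bw),
                    min_flux = as.numeric(minf),
                    score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "log_base") <- log_base
  class(out) <- c("edge_score_table", "data.frame")
  out
}

#' Select a tau-fraction of GGN flux to form the context network
#'
#' Restricts the edge-score table to the GGN, ranks edges by descending
#' minimum flux (strongest propagation/confidence first; ties broken by
#' node ids for determinism), computes the total score mass
#' `F = sum(f(e))` over finite-score GGN edges, and selects edges in rank
#' order until the running sum of `f(e)` reaches `tau * F`; the edge that
#' first reaches the budget is included, so `tau = 1` selects every
#' finite-score edge and `tau = 0` selects none.  Isolated nodes are
#' dropped: the context network's nodes are the endpoints of selected
#' edges.
#'
#' @param ggn a [build_ggn()] result (or any network object).
#' @param scores an [compute_edge_flux()] table computed on a graph
#'   containing the GGN.
#' @param tau fraction of total flux-score mass to retain, in `[0, 1]`.
#' @param literal_ranking rank by descending `f(e)` (ascending min-flux)
#'   instead; admits the weakest edges first and exists only to mirror the
#'   literal index convention of the selection formula (see the vignette).
#' @return object of class `context_network`: list with `network` (an
#'   interactome), `tau`, `total_flux` (F), and `scores` (score rows of the
#'   selected edges with their `selected_rank`).
#' @export
select_edges <- function(ggn, scores, tau = 0.5, literal_ranking = FALSE) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau < 0 || tau > 1) {
    stop("'tau' must be a single number in [0, 1]", call. = FALSE)
  }
  net <- as_interactome(ggn)
  empty <- function(F = 0) {
    s <- data.frame(from = character(), to = character(),
                    confidence = numeric(), flux_forward = numeric(),
                    flux_backward = numeric(), min_flux = numeric(),
                    score = numeric(), selected_rank = integer(),
                    stringsAsFactors = FALSE)
    structure(list(network = interactome(character(), character()),
                   tau = tau, total_flux = F, scores = s,
                   log_base = attr(scores, "log_base")),
              class = "context_network")
  }
  if (nrow(net$edges) == 0L) {
    warning("GGN is empty; context network is empty", call. = FALSE)
    return(empty())
  }
  idx <- match(edge_key(net$edges$from, net$edges$to),
               edge_key(scores$from, scores$to))
  if (anyNA(idx)) {
    stop("score table does not cover every GGN edge", call. = FALSE)
  }
  s <- scores[idx, , drop = FALSE]
  s <- s[is.finite(s$score), , drop = FALSE]
  F_total <- sum(s$score)
  if (nrow(s) == 0L || tau == 0) {
    return(empty(F_total))
  }
  o <- if (literal_ranking) order(s$min_flux, s$from, s$to)
       else order(-s$min_flux, s$from, s$to)
  s <- s[o, , drop = FALSE]
  if (F_total <= 0) {
    j <- nrow(s)                      # zero mass: budget holds trivially
  } else {
    cum <- cumsum(s$score)
    j <- which(cum >= tau * F_total - 1e-12)[1L]
    if (is.na(j)) j <- nrow(s)
  }
  sel <- s[seq_len(j), , drop = FALSE]
  sel$selected_rank <- seq_len(j)
  rownames(sel) <- NULL
  structure(list(network = interactome(sel$from, sel$to, sel$confidence),
                 tau = tau, total_flux = F_total, scores = sel,
                 log_base = attr(scores, "log_base")),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat("context network: ", length(x$network$nodes), " nodes, ",
      nrow(x$network$edges), " edges (tau = ", x$tau,
      ", F = ", sprintf("%.4g", x$total_flux), ")\n", sep = "")
  invisible(x)
}

#' Infer a context-specific network
#'
#' Runs the full pipeline: (i) graphlet census against the permutation null
#' and GGN construction; (ii) Personalized PageRank from the seeds over the
#' reference interactome and bidirectional edge-flux scoring; (iii)
#' tau-fraction edge selection on the GGN.  All stages share `rng_seed`, so
#' reruns with identical inputs are bit-identical.
#'
#' @inheritParams graphlet_significance
#' @inheritParams personalized_pagerank
#' @inheritParams select_edges
#' @param log_base see [compute_edge_flux()].
#' @return object of class `flux_inference`: list with `ggn`, `census`,
#'   `propagation`, `scores`, `network` (the context network) and `params`.
#' @examples
#' inst <- generate_benchmark(n_nodes = 120, pathway_size = 10,
#'                            seed_fraction = 0.6, rng_seed = 3)
#' fit <- infer(inst$interactome, inst$seeds, n_permutations = 20,
#'              rng_seed = 3)
#' fit$network
#' @export
infer <- function(graph, seeds, tau = 0.5, damping = 0.85,
                  n_permutations = 100L, alpha_z = 1.65, swap_factor = 10,
                  log_base = c("10", "e"), teleport = c("seeds", "uniform"),
                  tolerance = 1e-8, max_iterations = 1000L,
                  literal_ranking = FALSE, rng_seed = 1L) {
  log_base <- match.arg(log_base)
  teleport <- match.arg(teleport)
  graph <- as_interactome(graph)
  census <- graphlet_significance(graph, seeds,
                                  n_permutations = n_permutations,
                                  alpha_z = alpha_z,
                                  swap_factor = swap_factor,
                                  rng_seed = rng_seed)
  ggn <- build_ggn(graph, seeds, census)
  prop <- personalized_pagerank(graph, seeds, damping = damping,
                                tolerance = tolerance,
                                max_iterations = max_iterations,
                                teleport = teleport)
  scores <- compute_edge_flux(graph, prop, log_base = log_base)
  network <- if (nrow(ggn$network$edges)) {
    select_edges(ggn, scores, tau = tau, literal_ranking = literal_ranking)
  } else {
    suppressWarnings(select_edges(ggn, scores, tau = tau))
  }
  structure(list(ggn = ggn, census = census, propagation = prop,
                 scores = scores, network = network,
                 params = list(tau = tau, damping = damping,
                               n_permutations = n_permutations,
                               alpha_z = alpha_z, swap_factor = swap_factor,
                               log_base = log_base, teleport = teleport,
                               tolerance = tolerance,
                               max_iterations = max_iterations,
                               literal_ranking = literal_ranking,
                               rng_seed = rng_seed)),
            class = "flux_inference")
}

#' @export
print.flux_inference <- function(x, ...) {
  cat("flux inference (tau = ", x$params$tau, ", damping = ",
      x$params$damping, ")\n", sep = "")
  print(x$ggn)
  print(x$network)
  invisible(x)
}
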