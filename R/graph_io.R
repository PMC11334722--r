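#' Construct a reference interactome
#'
#' An interactome is an undirected, simple, confidence-weighted graph
#' \eqn{R(V_R, E_R, c(e))}: node identifiers are opaque case-sensitive
#' strings, edges are unordered pairs, and every confidence lies in
#' \eqn{(0, 1]}.  Self-loops are dropped and duplicate pairs are collapsed
#' keeping the maximum confidence (confidence is evidence strength, so the
#' maximum is conservative toward inclusion).  Directed input is thereby
#' symmetrized.
#'
#' @param from,to character vectors of edge endpoints.
#' @param confidence numeric vector of per-edge confidences in `(0, 1]`, or
#'   `NULL` to use `default_confidence` for every edge.
#' @param default_confidence confidence assigned to edges without one.
#' @return An object of class `interactome`: a list with `nodes` (sorted
#'   character vector) and `edges` (data frame with columns `from`, `to`,
#'   `confidence`, endpoints sorted within and across rows).
#' @examples
#' ix <- interactome(c("A", "B"), c("B", "C"), c(0.9, 0.8))
#' n_edges(ix)
#' @export
interactome <- function(from, to, confidence = NULL, default_confidence = 1.0) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) {
    stop("'from' and 'to' must have equal length", call. = FALSE)
  }
  if (is.null(confidence)) {
    confidence <- rep(default_confidence, length(from))
  }
  confidence <- as.numeric(confidence)
  if (length(confidence) != length(from)) {
    stop("'confidence' must match the number of edges", call. = FALSE)
  }
  check_confidence(confidence)
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b                        # drop self-loops
  a <- a[keep]; b <- b[keep]; confidence <- confidence[keep]
  if (length(a)) {
    # collapse duplicates keeping the maximum confidence
    o <- order(a, b, -confidence)
    a <- a[o]; b <- b[o]; confidence <- confidence[o]
    dup <- duplicated(paste(a, b, sep = "\r"))
    a <- a[!dup]; b <- b[!dup]; confidence <- confidence[!dup]
  }
  edges <- data.frame(from = a, to = b, confidence = confidence,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(a, b))), edges = edges),
            class = "interactome")
}

check_confidence <- function(confidence) {
  bad <- !is.finite(confidence) | confidence <= 0 | confidence > 1
  if (any(bad)) {
    stop("confidence values must lie in (0, 1]; offending values: ",
         paste(utils::head(confidence[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.interactome <- function(x, ...) {
  cat("interactome:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of nodes / edges of a network object
#'
#' @param x an `interactome`, `ggn` or `context_network`.
#' @return integer count.
#' @export
n_nodes <- function(x) length(as_interactome(x)$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(x) nrow(as_interactome(x)$edges)

#' Coerce a network object to its underlying interactome
#'
#' @param x an `interactome`, or a `ggn` / `context_network` wrapper.
#' @return the underlying `interactome`.
#' @export
as_interactome <- function(x) {
  if (inherits(x, "interactome")) return(x)
  if (is.list(x) && inherits(x$network, "interactome")) return(x$network)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an interactome", call. = FALSE)
}

#' Node degrees in an interactome
#'
#' @param x a network object.
#' @param nodes optional character vector; degrees are reported for these
#'   nodes (0 for nodes absent from `x`).
#' @return named integer vector of degrees.
#' @export
node_degree <- function(x, nodes = NULL) {
  x <- as_interactome(x)
  if (is.null(nodes)) nodes <- x$nodes
  d <- table(factor(c(x$edges$from, x$edges$to), levels = nodes))
  stats::setNames(as.integer(d), nodes)
}

#' Convert an interactome to an igraph graph
#'
#' Edge confidences are carried in the `confidence` edge attribute.
#'
#' @param x a network object.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(x) {
  x <- as_interactome(x)
  igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                vertices = data.frame(name = x$nodes))
}

# Induced restriction of an interactome to an explicit edge subset
# (data frame with from/to columns); confidences are looked up in `x`.
restrict_interactome <- function(x, edge_from, edge_to) {
  key <- edge_key(edge_from, edge_to)
  full <- edge_key(x$edges$from, x$edges$to)
  idx <- match(unique(key), full)
  if (anyNA(idx)) {
    stop("edge subset contains edges absent from the interactome",
         call. = FALSE)
  }
  e <- x$edges[sort(idx), , drop = FALSE]
  interactome(e$from, e$to, e$confidence)
}

#' Read a reference interactome from a tab-separated edge list
#'
#' Expects 2 or 3 tab-separated columns per row: `node_a`, `node_b` and an
#' optional confidence in `(0, 1]`.  Lines starting with `#` are treated as
#' comments/headers.  Rows missing the third column receive
#' `default_confidence` (an unweighted interactome becomes uniformly
#' weighted).  Self-loops are dropped and duplicate pairs collapsed keeping
#' the maximum confidence, so the result is independent of row order.
#'
#' @param path file path.
#' @param default_confidence confidence for rows without a third column.
#' @return an [interactome()].
#' @export
load_interactome <- function(path, default_confidence = 1.0) {
  check_confidence(default_confidence)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(interactome(character(), character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop("parse error at line ", keep[bad[1L]], ": expected 2 or 3 ",
         "tab-separated fields, found ", nf[bad[1L]], call. = FALSE)
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  conf <- rep(default_confidence, length(fields))
  has3 <- nf == 3L
  if (any(has3)) {
    raw <- vapply(fields[has3], `[[`, "", 3L)
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      stop("parse error at line ", keep[has3][which(is.na(val))[1L]],
           ": confidence is not numeric", call. = FALSE)
    }
    conf[has3] <- val
  }
  check_confidence(conf)
  interactome(from, to, conf)
}

#' Construct a seed set
#'
#' Seeds are the omic hits that drive inference.  Weights must be positive;
#' seeds without a weight get the default of 1.0.  Seeds absent from the
#' interactome are dropped (with a warning) and reported through `coverage`,
#' the fraction of input seeds retained.
#'
#' @param nodes character vector of seed identifiers.
#' @param weights positive numeric weights, or `NULL` for all-1.0.
#' @param interactome optional [interactome()]; when given, seeds outside it
#'   are excluded.
#' @return object of class `seed_set`: list with `weights` (named numeric),
#'   `coverage`, `n_input`, `dropped`.
#' @export
seed_set <- function(nodes, weights = NULL, interactome = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    keep <- !duplicated(nodes)
    if (!is.null(weights)) weights <- weights[keep]
    nodes <- nodes[keep]
  }
  if (is.null(weights)) weights <- rep(1.0, length(nodes))
  weights <- as.numeric(weights)
  if (length(weights) != length(nodes)) {
    stop("'weights' must match 'nodes'", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("seed weights must be positive and finite", call. = FALSE)
  }
  n_input <- length(nodes)
  dropped <- character()
  if (!is.null(interactome)) {
    interactome <- as_interactome(interactome)
    inside <- nodes %in% interactome$nodes
    dropped <- nodes[!inside]
    if (length(dropped)) {
      warning(length(dropped), " of ", n_input,
              " seed(s) absent from the interactome were dropped",
              call. = FALSE)
    }
    nodes <- nodes[inside]
    weights <- weights[inside]
  }
  if (!length(nodes)) {
    stop("no seeds remain after filtering against the interactome",
         call. = FALSE)
  }
  o <- order(nodes)
  structure(list(weights = stats::setNames(weights[o], nodes[o]),
                 coverage = if (n_input) length(nodes) / n_input else NA_real_,
                 n_input = n_input,
                 dropped = dropped),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("seed_set:", length(x$weights), "seeds (coverage ",
      sprintf("%.3f", x$coverage), ")\n", sep = "")
  invisible(x)
}

#' Read a seed table
#'
#' One or two tab-separated columns: node id and an optional positive
#' weight (default 1.0).  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param interactome [interactome()] used to filter seeds; seeds absent
#'   from it are dropped with a warning and zero retained seeds is an error.
#' @return a [seed_set()].
#' @export
load_seeds <- function(path, interactome) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) stop("seed file '", path, "' is empty", call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 1L | nf > 2L)) {
    bad <- which(nf < 1L | nf > 2L)[1L]
    stop("parse error at line ", keep[bad], ": expected 1 or 2 fields",
         call. = FALSE)
  }
  nodes <- vapply(fields, `[[`, "", 1L)
  weights <- rep(1.0, length(nodes))
  has2 <- nf == 2L
  if (any(has2)) {
    val <- suppressWarnings(as.numeric(vapply(fields[has2], `[[`, "", 2L)))
    if (anyNA(val)) {
      stop("parse error at line ", keep[has2][which(is.na(val))[1L]],
           ": weight is not numeric", call. = FALSE)
    }
    weights[has2] <- val
  }
  seed_set(nodes, weights, interactome = interactome)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: `term<TAB>description<TAB>gene1<TAB>gene2...`, one set per
#' line.  Empty sets are rejected.
#'
#' @param path file path.
#' @param universe optional character vector of background nodes.
#' @return object of class `annotation_collection`: list with `sets` (named
#'   list of character vectors), `descriptions` (named character) and
#'   `universe` (or `NULL`).
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("GMT parse error: every line needs term, description and >=1 gene",
         call. = FALSE)
  }
  terms <- vapply(fields, `[[`, "", 1L)
  descs <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  annotation_collection(stats::setNames(sets, terms),
                        stats::setNames(descs, terms), universe)
}

#' @rdname read_gmt
#' @param sets named list of non-empty character vectors (term -> members).
#' @param descriptions optional named character vector of term names.
#' @export
annotation_collection <- function(sets, descriptions = NULL, universe = NULL) {
  if (!length(sets) || is.null(names(sets))) {
    stop("'sets' must be a non-empty named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) {
    stop("annotation sets must be non-empty", call. = FALSE)
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, descriptions = descriptions,
                 universe = universe),
            class = "annotation_collection")
}

#' Write gene sets in GMT format
#' @param annotations an `annotation_collection`.
#' @param path output file path.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$sets), function(term) {
    paste(c(term, annotations$descriptions[[term]] %||% term,
            annotations$sets[[term]]), collapse = "\t")
  }, "")
  atomic_write(lines, path)
}

#' Write a network to disk
#'
#' TSV output carries columns `node_a`, `node_b`, `confidence`, `min_flux`,
#' `f_e`, `selected_rank`; the flux columns are `NA` for plain interactomes.
#' GraphML output carries the same attributes on edges.  Numbers are written
#' with 15 significant digits so a TSV round trip reproduces confidences and
#' scores exactly for all practical purposes.
#'
#' @param network an `interactome`, `ggn` or `context_network`.
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  x <- as_interactome(network)
  e <- x$edges
  if (inherits(network, "context_network") && nrow(e)) {
    s <- network$scores
    idx <- match(edge_key(e$from, e$to), edge_key(s$from, s$to))
    e$min_flux <- s$min_flux[idx]
    e$f_e <- s$score[idx]
    e$selected_rank <- s$selected_rank[idx]
  } else {
    e$min_flux <- rep(NA_real_, nrow(e))
    e$f_e <- rep(NA_real_, nrow(e))
    e$selected_rank <- rep(NA_integer_, nrow(e))
  }
  if (format == "tsv") {
    header <- "#node_a\tnode_b\tconfidence\tmin_flux\tf_e\tselected_rank"
    rows <- if (nrow(e)) {
      paste(e$from, e$to, fmt_num(e$confidence), fmt_num(e$min_flux),
            fmt_num(e$f_e), e$selected_rank, sep = "\t")
    } else character()
    atomic_write(c(header, rows), path)
  } else {
    g <- as_igraph(x)
    if (nrow(e)) {
      igraph::E(g)$min_flux <- e$min_flux
      igraph::E(g)$f_e <- e$f_e
      igraph::E(g)$selected_rank <- e$selected_rank
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path TSV file produced by `write_network(..., format = "tsv")`
#'   (plain 2-3 column edge lists are accepted too).
#' @return a list with `network` (an [interactome()]) and `scores` (data
#'   frame with `min_flux`, `score`, `selected_rank`, or `NULL` when the
#'   file carries no flux columns).
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(list(network = interactome(character(), character()),
                scores = NULL))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf <= 3L)) {
    return(list(network = load_interactome(path), scores = NULL))
  }
  if (any(nf != 6L)) {
    stop("parse error: mixed column counts in '", path, "'", call. = FALSE)
  }
  getn <- function(i) as.numeric(vapply(fields, `[[`, "", i))
  # flux columns may legitimately hold NA (plain networks) or Inf
  getn_na <- function(i) suppressWarnings(getn(i))
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  net <- interactome(from, to, getn(3L))
  scores <- data.frame(from = pmin(from, to), to = pmax(from, to),
                       min_flux = getn_na(4L), score = getn_na(5L),
                       selected_rank = suppressWarnings(
                         as.integer(vapply(fields, `[[`, "", 6L))),
                       stringsAsFactors = FALSE)
  list(network = net, scores = scores)
}
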