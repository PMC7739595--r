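#' Directed acyclic graphs over named nodes
#'
#' A `bn_dag` is a lightweight container for a directed acyclic graph: a
#' character vector of node names and a two-column character matrix of
#' directed arcs (`from`, `to`).  It is the structural component G of a
#' Bayesian network.
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix or data frame of directed arcs;
#'   may have zero rows.
#' @return An object of class `bn_dag` with elements `nodes` and `arcs`.
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' parents(g, "b")
#' @export
dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs)) {
    bad <- !(arcs %in% nodes)
    if (any(bad)) stop("arc endpoints not in node set: ",
                       paste(unique(arcs[bad]), collapse = ", "))
    if (any(arcs[, 1L] == arcs[, 2L])) stop("self-arcs are not allowed")
    key <- paste(arcs[, 1L], arcs[, 2L], sep = "\r")
    if (anyDuplicated(key)) stop("duplicate arcs are not allowed")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (!is_acyclic(g)) stop("graph contains a directed cycle")
  g
}

# Normalise NULL / data.frame / matrix input into a 2-column character matrix.
as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || NROW(arcs) == 0L) {
    return(matrix(character(), 0L, 2L, dimnames = list(NULL, c("from", "to"))))
  }
  arcs <- as.matrix(arcs)
  storage.mode(arcs) <- "character"
  if (ncol(arcs) != 2L) stop("arcs must have two columns (from, to)")
  colnames(arcs) <- c("from", "to")
  arcs
}

#' @rdname dag
#' @param x a `bn_dag`.
#' @export
print.bn_dag <- function(x, ...) {
  cat("Directed acyclic graph:", length(x$nodes), "nodes,",
      nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @rdname dag
#' @param g a `bn_dag`.
#' @param node a node name.
#' @export
parents <- function(g, node) unname(g$arcs[g$arcs[, 2L] == node, 1L])

#' @rdname dag
#' @export
children <- function(g, node) unname(g$arcs[g$arcs[, 1L] == node, 2L])

# Acyclicity by repeated removal of in-degree-0 nodes (Kahn's algorithm).
# Works on a plain node/arc pair so it can vet candidate structures cheaply.
acyclic_arcs <- function(nodes, arcs) {
  if (NROW(arcs) == 0L) return(TRUE)
  from <- match(arcs[, 1L], nodes)
  to <- match(arcs[, 2L], nodes)
  n <- length(nodes)
  indeg <- tabulate(to, nbins = n)
  alive <- rep(TRUE, length(from))
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    out <- which(alive & from == v)
    for (e in out) {
      alive[e] <- FALSE
      indeg[to[e]] <- indeg[to[e]] - 1L
      if (indeg[to[e]] == 0L) queue <- c(queue, to[e])
    }
  }
  removed == n
}

#' Test a graph for acyclicity
#' @param g a `bn_dag` (or list with `nodes` and `arcs`).
#' @return `TRUE` if the directed graph has no cycle.
#' @export
is_acyclic <- function(g) acyclic_arcs(g$nodes, g$arcs)

#' Topological ordering of a DAG
#' @param g a `bn_dag`.
#' @return node names ordered so every arc points forward.
#' @export
topological_order <- function(g) {
  nodes <- g$nodes
  arcs <- g$arcs
  n <- length(nodes)
  to <- match(arcs[, 2L], nodes)
  from <- match(arcs[, 1L], nodes)
  indeg <- tabulate(to, nbins = n)
  order <- integer(0)
  queue <- sort(which(indeg == 0L))
  alive <- rep(TRUE, length(from))
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, v)
    out <- which(alive & from == v)
    for (e in out) {
      alive[e] <- FALSE
      indeg[to[e]] <- indeg[to[e]] - 1L
      if (indeg[to[e]] == 0L) queue <- c(queue, to[e])
    }
  }
  if (length(order) != n) stop("graph is cyclic; no topological order")
  nodes[order]
}

#' Markov blanket of a node
#'
#' The Markov blanket is the set of parents, children, and children's other
#' parents (spouses) of a node; conditioning on it renders the node
#' independent of the rest of the network.
#'
#' @param g a `bn_dag`.
#' @param node node name.
#' @return character vector of blanket node names (sorted, without `node`).
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "c"), c("b", "c")))
#' markov_blanket(g, "a")  # spouse "b" through common child "c"
#' @export
markov_blanket <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  ch <- children(g, node)
  spouses <- unlist(lapply(ch, function(c) parents(g, c)), use.names = FALSE)
  setdiff(sort(unique(c(parents(g, node), ch, spouses))), node)
}

#' Export a DAG in DOT format
#' @param g a `bn_dag`.
#' @param file optional path; if `NULL` the DOT text is returned.
#' @param labels optional named vector of arc labels keyed "from->to".
#' @return DOT source, invisibly when written to file.
#' @export
write_dot <- function(g, file = NULL, labels = NULL) {
  body <- c(paste0("  \"", g$nodes, "\";"))
  if (nrow(g$arcs)) {
    lab <- rep("", nrow(g$arcs))
    if (!is.null(labels)) {
      key <- paste0(g$arcs[, 1L], "->", g$arcs[, 2L])
      hit <- key %in% names(labels)
      lab[hit] <- paste0(" [label=\"", labels[key[hit]], "\"]")
    }
    body <- c(body, paste0("  \"", g$arcs[, 1L], "\" -> \"",
                           g$arcs[, 2L], "\"", lab, ";"))
  }
  txt <- paste(c("digraph bn {", body, "}"), collapse = "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Serialise / read a DAG as adjacency-list JSON
#' @param g a `bn_dag`.
#' @param file path to write to (`write_dag_json`) or read from.
#' @return `read_dag_json` returns a `bn_dag`.
#' @export
write_dag_json <- function(g, file) {
  adj <- lapply(stats::setNames(g$nodes, g$nodes), function(v) children(g, v))
  jsonlite::write_json(list(nodes = g$nodes, children = adj), file,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  arcs <- do.call(rbind, lapply(names(x$children), function(v) {
    ch <- x$children[[v]]
    if (length(ch)) cbind(from = v, to = ch) else NULL
  }))
  dag(x$nodes, arcs)
}
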