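#' Construct an undirected protein interactome
#'
#' The central graph container of the pipeline: an undirected, simple graph of
#' protein/gene symbols. Edges are stored canonically (lexicographically
#' ordered endpoints, deduplicated, self-loops rejected) so that two
#' interactomes with the same node and edge sets compare identical regardless
#' of input order. Symbols are upper-cased: node identity is case-normalised
#' string equality, with no identifier-mapping service behind it.
#'
#' @param edges two-column character matrix or data.frame of endpoint pairs;
#'   may have zero rows.
#' @param nodes optional character vector of node symbols; defaults to the
#'   union of edge endpoints. Extra symbols become isolated nodes.
#' @return An object of class `interactome`: a list with elements `nodes`
#'   (character) and `edges` (data.frame with columns `from`, `to`).
#' @examples
#' g <- interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
#' g$nodes
#' @export
interactome <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (ncol(edges) < 2L)
      stop("edges must have two columns (endpoints)")
    a <- toupper(as.character(edges[[1L]]))
    b <- toupper(as.character(edges[[2L]]))
    if (anyNA(a) || anyNA(b)) stop("edge endpoints must not be NA")
    loop <- a == b
    if (any(loop)) stop("self-loops are not allowed: ", a[which(loop)[1L]])
    ed <- data.frame(from = pmin(a, b), to = pmax(a, b),
                     stringsAsFactors = FALSE)
    ed <- unique(ed)
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
  }
  nd <- sort(unique(c(toupper(as.character(nodes)), ed$from, ed$to)))
  structure(list(nodes = nd, edges = ed), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges of an interactome
#'
#' @param g an `interactome`.
#' @return Named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(g) {
  stopifnot(inherits(g, "interactome"))
  c(nodes = length(g$nodes), edges = nrow(g$edges))
}

#' Convert an interactome to an igraph graph
#'
#' Isolated nodes are preserved as degree-0 vertices.
#'
#' @param g an `interactome`.
#' @return An undirected `igraph` graph with vertex `name` attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "interactome"))
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

#' Convert an igraph graph to an interactome
#'
#' @param graph an undirected `igraph` graph with named vertices.
#' @return An `interactome`.
#' @export
from_igraph <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  nd <- igraph::V(graph)$name
  ed <- igraph::as_edgelist(graph, names = TRUE)
  interactome(ed, nodes = nd)
}

#' Induced subgraph of an interactome
#'
#' Keeps the requested nodes (those present in the graph) and every edge with
#' both endpoints among them.
#'
#' @param g an `interactome`.
#' @param nodes character vector of node symbols (case-insensitive).
#' @return An `interactome`.
#' @export
induced_network <- function(g, nodes) {
  stopifnot(inherits(g, "interactome"))
  keep <- intersect(g$nodes, toupper(as.character(nodes)))
  ed <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, , drop = FALSE]
  interactome(ed, nodes = keep)
}
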