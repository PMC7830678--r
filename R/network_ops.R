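# Drug/disease network assembly: compound-target bipartite construction,
# seed expansion against a background interactome (seeds + direct
# interactors, induced edges), and merge-intersection of two networks
# (Cytoscape merge semantics: only nodes and edges present in both survive).

#' Build a compound-target bipartite network
#'
#' Links each candidate compound to its mapped protein targets. Map entries
#' whose compound is not among the candidates are dropped with a warning;
#' candidates with no mapping stay as isolated compound nodes.
#'
#' @param candidates a `candidate_set` (see [screen_ingredients()]).
#' @param target_map named list compound -> character vector of target
#'   symbols.
#' @return A `bipartite_network`: list with `compounds`, `targets` (the
#'   putative drug-target list passed downstream), and `links` (data.frame
#'   compound/target).
#' @export
build_bipartite <- function(candidates, target_map) {
  comp <- unique(as.character(candidates$compound))
  if (is.null(names(target_map)) && length(target_map) > 0L)
    stop("target_map must be a named list (compound -> targets)")
  unknown <- setdiff(names(target_map), comp)
  if (length(unknown) > 0L) {
    warning("dropping map entries for non-candidate compound(s): ",
            paste(unknown, collapse = ", "))
    target_map <- target_map[setdiff(names(target_map), unknown)]
  }
  links <- do.call(rbind, c(list(
    data.frame(compound = character(0), target = character(0),
               stringsAsFactors = FALSE)),
    lapply(names(target_map), function(cp) {
      tg <- unique(toupper(as.character(target_map[[cp]])))
      if (length(tg) == 0L) return(NULL)
      data.frame(compound = cp, target = tg, stringsAsFactors = FALSE)
    })))
  links <- unique(links)
  rownames(links) <- NULL
  structure(list(compounds = comp,
                 targets = sort(unique(links$target)),
                 links = links),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d compounds, %d targets, %d links\n",
              length(x$compounds), length(x$targets), nrow(x$links)))
  invisible(x)
}

#' Degree of each target in a bipartite network
#'
#' The number of distinct candidate compounds hitting each target.
#'
#' @param network a `bipartite_network`.
#' @return named integer vector over target nodes.
#' @export
target_degree <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  tab <- table(factor(network$links$target, levels = network$targets))
  stats::setNames(as.integer(tab), names(tab))
}

#' Expand a seed gene set against an interactome
#'
#' Returns the subgraph induced on the seeds plus their interactors within
#' `depth` steps (default 1: direct interactors), i.e. every interactome edge
#' with both endpoints in that node set. Seeds absent from the interactome
#' are retained as isolated nodes and reported via a message.
#'
#' @param seeds non-empty character vector of gene symbols.
#' @param interactome an `interactome`.
#' @param depth neighborhood radius; default 1.
#' @return An `interactome`.
#' @export
expand_seed_network <- function(seeds, interactome, depth = 1L) {
  stopifnot(inherits(interactome, "interactome"))
  seeds <- unique(toupper(as.character(seeds)))
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  missing <- setdiff(seeds, interactome$nodes)
  if (length(missing) > 0L)
    message(length(missing), " seed(s) absent from the interactome kept as ",
            "isolated nodes")
  present <- intersect(seeds, interactome$nodes)
  nodes <- present
  if (length(present) > 0L && depth > 0L) {
    g <- as_igraph(interactome)
    hood <- igraph::ego(g, order = depth, nodes = present)
    nodes <- unique(c(present, unlist(lapply(hood, names))))
  }
  sub <- induced_network(interactome, nodes)
  interactome(sub$edges, nodes = c(sub$nodes, missing))
}

#' Intersect two interactomes
#'
#' Merge-intersection: kept nodes are those in both networks and kept edges
#' those present in both edge sets (not all induced edges), the semantics of
#' a Cytoscape network-merge intersection.
#'
#' @param a,b `interactome` objects.
#' @return An `interactome`.
#' @export
intersect_networks <- function(a, b) {
  stopifnot(inherits(a, "interactome"), inherits(b, "interactome"))
  nodes <- intersect(a$nodes, b$nodes)
  key_a <- paste(a$edges$from, a$edges$to, sep = "\r")
  key_b <- paste(b$edges$from, b$edges$to, sep = "\r")
  ed <- a$edges[key_a %in% key_b, , drop = FALSE]
  interactome(ed, nodes = nodes)
}
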