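# Two-stage median-centrality screening and hub selection, the topological
# core of the pipeline: stage 1 keeps nodes with degree >= factor x median
# degree of the merged network; stage 2 keeps nodes strictly above the
# medians of degree (DC), betweenness (BC) and closeness (CC), recomputed on
# the stage-1 network; hubs are the intersection of the per-metric top-k
# lists over the core-target network.

#' Degree, betweenness and closeness centrality of every node
#'
#' Computed on the largest connected component (closeness is undefined
#' across components); nodes outside it are reported via a message and
#' excluded. Definitions: DC(v) = |neighbors(v)|; BC(v) = sum over unordered
#' pairs s != t != v of the fraction of s-t geodesics through v (Brandes,
#' unnormalized); CC(v) = (n_c - 1) / sum of geodesic distances from v, for a
#' component of n_c nodes.
#'
#' @param graph a non-empty `interactome`.
#' @return A `centrality_table`: data.frame with columns node, dc, bc, cc
#'   (one row per component node, in node order).
#' @examples
#' tri <- interactome(data.frame(from = c("a", "b", "c"),
#'                               to = c("b", "c", "a")))
#' compute_centralities(tri)
#' @export
compute_centralities <- function(graph) {
  stopifnot(inherits(graph, "interactome"))
  if (length(graph$nodes) == 0L) stop("graph is empty")
  g <- as_igraph(graph)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    keep <- which(comp$membership == which.max(comp$csize))
    message(sum(comp$csize) - length(keep),
            " node(s) outside the largest component excluded from centrality")
    g <- igraph::induced_subgraph(g, keep)
  }
  n <- igraph::vcount(g)
  cc <- if (n == 1L) stats::setNames(0, igraph::V(g)$name)
        else igraph::closeness(g, normalized = TRUE)
  out <- data.frame(node = igraph::V(g)$name,
                    dc = as.numeric(igraph::degree(g)),
                    bc = as.numeric(igraph::betweenness(g, directed = FALSE)),
                    cc = as.numeric(cc),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Stage-1 screen: keep nodes with degree >= factor x median degree
#'
#' The median is taken over the degrees of ALL nodes of the input graph
#' (mean of the two middle values for even counts), and the subgraph induced
#' on the surviving nodes is returned. `cmp = "gt"` switches the comparator
#' to strict.
#'
#' @param graph a non-empty `interactome`.
#' @param factor multiplier on the median degree; default 2.
#' @param cmp `"ge"` (default, inclusive) or `"gt"` (strict).
#' @return An `interactome` (possibly empty); attribute `"median_dc"` holds
#'   the median degree used.
#' @export
filter_by_degree <- function(graph, factor = 2, cmp = c("ge", "gt")) {
  stopifnot(inherits(graph, "interactome"))
  cmp <- match.arg(cmp)
  if (length(graph$nodes) == 0L) stop("graph is empty")
  deg <- node_degrees(graph)
  med <- stats::median(deg)
  thr <- factor * med
  keep <- if (cmp == "ge") names(deg)[deg >= thr] else names(deg)[deg > thr]
  out <- induced_network(graph, keep)
  attr(out, "median_dc") <- med
  out
}

node_degrees <- function(graph) {
  counts <- table(factor(c(graph$edges$from, graph$edges$to),
                         levels = graph$nodes))
  stats::setNames(as.numeric(counts), graph$nodes)
}

#' Stage-2 screen: core targets above all three centrality medians
#'
#' Recomputes DC/BC/CC and their medians on the input graph (the stage-1
#' network, not the merged parent) and returns the nodes strictly exceeding
#' all three medians. On any vertex-transitive graph the result is empty: no
#' node strictly exceeds a value shared by all.
#'
#' @param graph a non-empty `interactome`.
#' @param cmp `"gt"` (default, strict) or `"ge"`.
#' @return character vector of core-target symbols; attribute `"medians"`
#'   holds the per-metric medians used.
#' @export
filter_core <- function(graph, cmp = c("gt", "ge")) {
  stopifnot(inherits(graph, "interactome"))
  cmp <- match.arg(cmp)
  if (length(graph$nodes) == 0L) stop("graph is empty")
  ct <- compute_centralities(graph)
  med <- c(dc = stats::median(ct$dc), bc = stats::median(ct$bc),
           cc = stats::median(ct$cc))
  keep <- if (cmp == "gt")
    ct$dc > med["dc"] & ct$bc > med["bc"] & ct$cc > med["cc"]
  else
    ct$dc >= med["dc"] & ct$bc >= med["bc"] & ct$cc >= med["cc"]
  out <- ct$node[keep]
  attr(out, "medians") <- med
  out
}

#' Hub targets: intersection of the per-metric top-k rankings
#'
#' For each of DC, BC and CC the table is ranked descending and the top `k`
#' nodes taken, INCLUDING every node tied with the k-th value (deterministic
#' and order-independent, rather than an arbitrary tie-break); the hub set is
#' the intersection of the three top lists.
#'
#' @param table a `centrality_table` from [compute_centralities()].
#' @param k list depth; default 10.
#' @return character vector of hub symbols (sorted).
#' @export
select_hubs <- function(table, k = 10L) {
  stopifnot(inherits(table, "centrality_table"))
  if (nrow(table) == 0L) stop("centrality table is empty")
  if (k < 1L) stop("k must be >= 1")
  top_k <- function(x) {
    if (length(x) <= k) return(table$node)
    cut <- sort(x, decreasing = TRUE)[k]
    table$node[x >= cut]
  }
  sort(intersect(intersect(top_k(table$dc), top_k(table$bc)),
                 top_k(table$cc)))
}

#' Full topological screen of a merged network
#'
#' Runs the two median stages and hub selection in sequence on a merged
#' drug/disease network: stage 1 by [filter_by_degree()], stage 2 by
#' [filter_core()] on the stage-1 network, and hubs by [select_hubs()] on
#' centralities of the core-target network (the subgraph of stage 1 induced
#' on the core targets).
#'
#' @param merged the merged `interactome` (stage 0).
#' @param degree_factor stage-1 multiplier; default 2.
#' @param k hub list depth; default 10.
#' @param stage1_cmp,stage2_cmp comparators for the two stages; defaults
#'   `"ge"` and `"gt"`.
#' @return A `screen_report`: list with `stage0`, `stage1`, `stage2_network`
#'   (interactomes), `core` and `hubs` (gene vectors), and `medians` (list of
#'   the medians used at each stage). Satisfies
#'   hubs ⊆ core ⊆ stage1 nodes ⊆ stage0 nodes.
#' @export
screen_topology <- function(merged, degree_factor = 2, k = 10L,
                            stage1_cmp = "ge", stage2_cmp = "gt") {
  stopifnot(inherits(merged, "interactome"))
  stage1 <- filter_by_degree(merged, factor = degree_factor, cmp = stage1_cmp)
  if (length(stage1$nodes) == 0L) {
    core <- character(0); hubs <- character(0)
    stage2_net <- stage1
    med2 <- c(dc = NA_real_, bc = NA_real_, cc = NA_real_)
  } else {
    core <- filter_core(stage1, cmp = stage2_cmp)
    med2 <- attr(core, "medians")
    stage2_net <- induced_network(stage1, core)
    hubs <- if (length(core) == 0L) character(0)
            else select_hubs(compute_centralities(stage2_net), k = k)
  }
  structure(list(stage0 = merged, stage1 = stage1,
                 stage2_network = stage2_net,
                 core = sort(as.character(core)), hubs = hubs,
                 medians = list(stage1_dc = attr(stage1, "median_dc"),
                                stage2 = med2)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  s0 <- network_size(x$stage0); s1 <- network_size(x$stage1)
  cat(sprintf(paste0("screen_report: merged %d/%d -> stage1 %d/%d -> ",
                     "core %d -> hubs %d\n"),
              s0["nodes"], s0["edges"], s1["nodes"], s1["edges"],
              length(x$core), length(x$hubs)))
  invisible(x)
}
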