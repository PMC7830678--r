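# Independent brute-force oracles used to cross-check the implementation.
# They deliberately avoid the code paths (igraph, stats::phyper,
# stats::p.adjust) they are checking.

# All-pairs geodesic enumeration by BFS: distances and geodesic counts,
# then DC/BC/CC from first principles. Assumes a connected graph.
oracle_centralities <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    adj[a, b] <- TRUE; adj[b, a] <- TRUE
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ])) {
        if (is.infinite(dist[s, w])) {
          dist[s, w] <- d + 1
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == d + 1) sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- unique(nxt); d <- d + 1
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(dist[, v], dist[v, ], "+") == dist
    contrib <- outer(sigma[, v], sigma[v, ]) / sigma
    contrib[!on_path | sigma == 0] <- 0
    contrib[v, ] <- 0; contrib[, v] <- 0
    bc[v] <- sum(contrib[upper.tri(contrib)])
  }
  data.frame(node = nodes,
             dc = rowSums(adj),
             bc = bc,
             cc = if (n == 1L) 0 else (n - 1) / rowSums(dist),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Random connected simple graph: random recursive spanning tree plus extra
# random edges. Deterministic under the caller's seed.
random_connected_graph <- function(n, extra = n) {
  stopifnot(n >= 2L)
  lab <- sprintf("N%03d", seq_len(n))
  tree <- cbind(lab[2:n],
                lab[vapply(2:n, function(i) sample.int(i - 1L, 1L),
                           integer(1))])
  a <- sample.int(n, extra, replace = TRUE)
  b <- sample.int(n, extra, replace = TRUE)
  keep <- a != b
  interactome(rbind(tree, cbind(lab[a[keep]], lab[b[keep]])))
}

# Hypergeometric upper tail by direct combinatorial ratio (exact at small N).
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Benjamini-Hochberg step-up recomputed from its definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Small seeded sim_config for fast tests; any field can be overridden.
tiny_config <- function(seed = 1, ...) {
  defaults <- list(n_nodes = 60, edges_per_new_node = 2, n_genes = 200,
                   n_de = 10, n_tumor = 5, n_normal = 5, n_terms = 10,
                   term_size_range = c(5, 20))
  do.call(sim_config,
          c(list(seed = seed), utils::modifyList(defaults, list(...))))
}
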