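cand <- function(compounds) {
  structure(data.frame(herb = "H", compound = compounds,
                       ob = 50, dl = 0.5, whitelisted = FALSE,
                       provenance = "threshold", stringsAsFactors = FALSE),
            class = c("candidate_set", "data.frame"))
}

test_that("interactome container canonicalises, rejects loops, stays simple", {
  g <- interactome(data.frame(from = c("b", "a", "B"), to = c("a", "c", "A")))
  expect_identical(g$nodes, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 2L)           # duplicate B-A collapsed
  expect_true(all(g$edges$from <= g$edges$to))
  expect_error(interactome(data.frame(from = "x", to = "x")), "self-loop")
})

test_that("bipartite construction counts shared targets correctly", {
  b <- build_bipartite(cand(c("c1", "c2")), list(c1 = "T", c2 = "T"))
  expect_equal(unname(target_degree(b)["T"]), 2L)

  b <- build_bipartite(cand(c("c1", "c2", "c3")),
                       list(c1 = c("A", "B"), c2 = "B", c3 = character(0)))
  expect_identical(b$targets, c("A", "B"))
  expect_equal(nrow(b$links), 3L)
  expect_equal(unname(target_degree(b)["B"]), 2L)

  empty <- build_bipartite(cand(c("c1", "c2")), list())
  expect_length(empty$targets, 0L)
  expect_equal(nrow(empty$links), 0L)
  expect_identical(empty$compounds, c("c1", "c2"))
})

test_that("map entries for unknown compounds are dropped with a warning", {
  expect_warning(b <- build_bipartite(cand("c1"),
                                      list(c1 = "A", ghost = "B")),
                 "ghost")
  expect_identical(b$targets, "A")
})

test_that("seed expansion is seeds plus direct interactors with induced edges", {
  path <- interactome(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "d")))
  ex <- expand_seed_network(c("a", "d"), path)
  expect_identical(ex$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(ex$edges), 3L)

  # seeds absent from the interactome survive as isolated nodes
  expect_message(ex2 <- expand_seed_network(c("a", "zz"), path), "absent")
  expect_true("ZZ" %in% ex2$nodes)
  expect_error(expand_seed_network(character(0), path), "non-empty")

  # seeding with every node reproduces the interactome
  all_net <- expand_seed_network(path$nodes, path)
  expect_identical(all_net$edges, path$edges)
  expect_identical(all_net$nodes, path$nodes)
})

test_that("expansion depth widens the neighborhood monotonically", {
  chain <- interactome(cbind(paste0("n", 1:9), paste0("n", 2:10)))
  for (d in 0:3) {
    ex <- expand_seed_network("n1", chain, depth = d)
    expect_identical(sort(ex$nodes), sort(toupper(paste0("n", 1:(d + 1)))))
  }
})

test_that("network intersection keeps only shared nodes and shared edges", {
  tri <- interactome(data.frame(from = c("x", "y", "x"),
                                to = c("y", "z", "z")))
  other <- interactome(data.frame(from = c("x", "y"), to = c("y", "zp")))
  out <- intersect_networks(tri, other)
  expect_identical(out$nodes, c("X", "Y"))
  expect_equal(nrow(out$edges), 1L)
  expect_identical(out$edges$from, "X")

  expect_identical(intersect_networks(tri, tri), tri)          # idempotent
  disjoint <- interactome(data.frame(from = "p", to = "q"))
  expect_equal(unname(network_size(intersect_networks(tri, disjoint))),
               c(0L, 0L))
})

test_that("intersection is commutative and bounded by both parents", {
  set.seed(13)
  for (i in 1:10) {
    a <- random_connected_graph(sample(5:25, 1))
    b <- random_connected_graph(sample(5:25, 1))
    ab <- intersect_networks(a, b)
    ba <- intersect_networks(b, a)
    expect_identical(ab$nodes, ba$nodes)
    expect_identical(ab$edges, ba$edges)
    expect_lte(nrow(ab$edges), min(nrow(a$edges), nrow(b$edges)))
    # expansion edge sets are subsets of the interactome's
    seeds <- sample(a$nodes, 2)
    ex <- expand_seed_network(seeds, a)
    expect_true(all(seeds %in% ex$nodes))
    key <- function(g) paste(g$edges$from, g$edges$to)
    expect_true(all(key(ex) %in% key(a)))
  }
})

test_that("SIF and edge-list round-trips preserve node and edge sets", {
  set.seed(3)
  g <- random_connected_graph(20)
  g <- interactome(g$edges, nodes = c(g$nodes, "LONER"))  # isolated node
  sif <- tempfile(fileext = ".sif")
  write_sif(g, sif)
  back <- read_sif(sif)
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$edges, g$edges)

  tsv <- tempfile(fileext = ".tsv")
  expect_warning(write_edges(g, tsv), "isolated")
  back2 <- read_edges(tsv)
  expect_identical(back2$edges, g$edges)
})
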