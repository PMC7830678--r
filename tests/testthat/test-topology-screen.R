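test_that("centralities on analytically solvable graphs", {
  tri <- interactome(data.frame(from = c("a", "b", "c"),
                                to = c("b", "c", "a")))
  ct <- compute_centralities(tri)
  expect_equal(ct$dc, rep(2, 3))
  expect_equal(ct$bc, rep(0, 3))
  expect_equal(ct$cc, rep(1, 3))

  path <- interactome(data.frame(from = c("a", "b"), to = c("b", "c")))
  ct <- compute_centralities(path)
  b <- ct[ct$node == "B", ]
  a <- ct[ct$node == "A", ]
  expect_equal(c(b$dc, b$bc, b$cc), c(2, 1, 1))
  expect_equal(c(a$dc, a$bc, a$cc), c(1, 0, 2 / 3))

  expect_error(compute_centralities(interactome()), "empty")
})

test_that("centrality is computed on the largest component only", {
  g <- interactome(data.frame(from = c("a", "b", "x"),
                              to = c("b", "c", "y")))
  expect_message(ct <- compute_centralities(g), "outside the largest")
  expect_identical(sort(ct$node), c("A", "B", "C"))
})

test_that("DC/BC/CC match the geodesic-enumeration oracle on random graphs", {
  set.seed(101)
  for (i in 1:25) {
    g <- random_connected_graph(sample(4:30, 1))
    got <- compute_centralities(g)
    want <- oracle_centralities(g)
    got <- got[match(want$node, got$node), ]
    expect_equal(got$dc, want$dc, tolerance = 1e-9)
    expect_equal(got$bc, want$bc, tolerance = 1e-9)
    expect_equal(got$cc, want$cc, tolerance = 1e-9)
  }
})

test_that("stage-1 degree filter: star, regular annihilation, identity", {
  star <- interactome(cbind(rep("hub", 4), paste0("leaf", 1:4)))
  out <- filter_by_degree(star)          # degrees {4,1,1,1,1}, median 1
  expect_identical(out$nodes, "HUB")
  expect_equal(nrow(out$edges), 0L)
  expect_equal(attr(out, "median_dc"), 1)

  c4 <- interactome(data.frame(from = c("a", "b", "c", "d"),
                               to = c("b", "c", "d", "a")))
  expect_length(filter_by_degree(c4)$nodes, 0L)   # all dc = 2, threshold 4
  expect_identical(filter_by_degree(c4, factor = 0)$edges, c4$edges)

  # even node count: median is the mean of the two middle degrees
  g <- interactome(data.frame(from = c("a", "a", "a", "b"),
                              to = c("b", "c", "d", "c")))
  expect_equal(attr(filter_by_degree(g), "median_dc"), 2)
})

test_that("core filter is empty on vertex-transitive graphs and matches a brute force on a barbell", {
  c5 <- interactome(cbind(paste0("v", 1:5), paste0("v", c(2:5, 1))))
  expect_length(filter_core(c5), 0L)
  k4 <- interactome(t(combn(paste0("k", 1:4), 2)))
  expect_length(filter_core(k4), 0L)
  single <- interactome(nodes = "solo")
  expect_length(filter_core(single), 0L)

  # two K4s joined through a 2-node bridge path
  k <- function(p, n) t(combn(paste0(p, 1:n), 2))
  barbell <- interactome(rbind(k("l", 4), k("r", 4),
                               cbind(c("l1", "b1", "b2"),
                                     c("b1", "b2", "r1"))))
  got <- filter_core(barbell)
  ct <- oracle_centralities(barbell)
  want <- ct$node[ct$dc > median(ct$dc) & ct$bc > median(ct$bc) &
                  ct$cc > median(ct$cc)]
  expect_identical(sort(as.character(got)), sort(want))
})

test_that("hub selection keeps boundary ties and saturates on small tables", {
  mk <- function(dc, bc, cc)
    structure(data.frame(node = paste0("n", seq_along(dc)), dc = dc,
                         bc = bc, cc = cc, stringsAsFactors = FALSE),
              class = c("centrality_table", "data.frame"))

  small <- mk(1:3, 1:3, 1:3)
  expect_length(select_hubs(small, k = 10), 3L)

  # node 15 leads every metric; nodes 2..15 fill distinct non-overlapping
  # top-10 slots per metric so only n15 is in all three
  dc <- c(1:14, 100); bc <- c(14:1, 100) / 10; cc <- c(7:1, 14:8, 100) / 100
  hubs <- select_hubs(mk(dc, bc, cc), k = 5)
  expect_identical(hubs, "n15")

  # identical rankings across metrics: result is that ranking's top-k
  hubs <- select_hubs(mk(1:15, (1:15) / 10, (1:15) / 100), k = 4)
  expect_identical(sort(hubs), sort(paste0("n", 12:15)))

  # ties at the k-th value are all kept
  tied <- mk(c(5, 5, 5, 1), c(5, 5, 5, 1), c(5, 5, 5, 1))
  expect_length(select_hubs(tied, k = 2), 3L)
})

test_that("screen output is nested and scale-invariant in BC", {
  set.seed(55)
  for (i in 1:10) {
    cfg <- sim_config(seed = i, n_nodes = sample(40:120, 1),
                      edges_per_new_node = sample(2:3, 1))
    g <- generate_interactome(cfg)
    rep <- screen_topology(g)
    expect_true(all(rep$hubs %in% rep$core))
    expect_true(all(rep$core %in% rep$stage1$nodes))
    expect_true(all(rep$stage1$nodes %in% rep$stage0$nodes))
  }

  # multiplying BC by a positive constant changes neither medians ranks
  ct <- compute_centralities(generate_interactome(sim_config(seed = 2,
                                                             n_nodes = 60)))
  scaled <- ct; scaled$bc <- scaled$bc * 1e6
  class(scaled) <- class(ct)
  expect_identical(select_hubs(ct, 10), select_hubs(scaled, 10))
})

test_that("planted high-centrality module survives into the core set", {
  hits <- vapply(1:10, function(s) {
    g <- generate_interactome(sim_config(seed = s, n_nodes = 150,
                                         edges_per_new_node = 2,
                                         n_module = 10))
    rep <- screen_topology(g)
    mean(attr(g, "module") %in% rep$core)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})
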