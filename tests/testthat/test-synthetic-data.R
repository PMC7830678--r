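test_that("config validation names the offending field", {
  expect_error(sim_config(n_nodes = 1), "n_nodes")
  expect_error(sim_config(edges_per_new_node = 0), "edges_per_new_node")
  expect_error(sim_config(n_nodes = 5, edges_per_new_node = 5),
               "edges_per_new_node")
  expect_error(sim_config(whitelist_rate = 1.2), "whitelist_rate")
  expect_error(sim_config(n_genes = 50, n_de = 50), "n_de")
  expect_error(sim_config(term_size_range = c(9, 3)), "term_size_range")
})

test_that("interactome generator: smallest case, determinism, simplicity", {
  g <- generate_interactome(sim_config(seed = 4, n_nodes = 2,
                                       edges_per_new_node = 1))
  expect_equal(unname(network_size(g)), c(2L, 1L))

  cfg <- sim_config(seed = 42, n_nodes = 80, edges_per_new_node = 2)
  g1 <- generate_interactome(cfg)
  g2 <- generate_interactome(cfg)
  expect_identical(g1$edges, g2$edges)

  # simple and connected
  expect_false(any(g1$edges$from == g1$edges$to))
  expect_identical(anyDuplicated(g1$edges), 0L)
  comp <- igraph::components(as_igraph(g1))
  expect_equal(comp$no, 1L)
})

test_that("preferential attachment yields a heavy-tailed degree distribution", {
  g <- generate_interactome(sim_config(seed = 9, n_nodes = 500,
                                       edges_per_new_node = 3))
  deg <- igraph::degree(as_igraph(g))
  expect_gte(max(deg), 5 * median(deg))
})

test_that("planted module nodes form a clique on top-degree nodes", {
  g <- generate_interactome(sim_config(seed = 5, n_nodes = 100,
                                       edges_per_new_node = 2,
                                       n_module = 6))
  module <- attr(g, "module")
  expect_length(module, 6L)
  sub <- induced_network(g, module)
  expect_equal(nrow(sub$edges), choose(6, 2))
})

test_that("compound table has the requested shape and whitelist boundaries", {
  cfg <- sim_config(seed = 2, n_herbs = 7, compounds_per_herb = 10)
  tab <- generate_compound_table(cfg)
  expect_equal(nrow(tab), 70L)
  expect_true(all(table(tab$herb) == 10L))
  expect_identical(generate_compound_table(cfg), tab)

  none <- generate_compound_table(sim_config(seed = 2, whitelist_rate = 0))
  expect_false(any(none$whitelisted))
  all_wl <- generate_compound_table(sim_config(seed = 2, whitelist_rate = 1))
  expect_true(all(all_wl$whitelisted))
})

test_that("whitelisted records survive an impossible threshold", {
  tab <- generate_compound_table(sim_config(seed = 8, whitelist_rate = 1))
  kept <- screen_ingredients(tab, ob_min = 101, dl_min = 1.01)
  expect_equal(nrow(kept), nrow(tab))
  expect_true(all(kept$provenance == "whitelist"))
})

test_that("expression cohorts share one planted gene list and are reproducible", {
  cfg <- tiny_config(seed = 6)
  e1 <- generate_expression(cfg)
  e2 <- generate_expression(cfg)
  expect_length(e1$cohorts, 3L)
  expect_identical(e1$planted, e2$planted)
  expect_identical(e1$cohorts[[2]]$values, e2$cohorts[[2]]$values)
  expect_length(e1$planted, cfg$n_de)
  # planted shift is present in tumor means of every cohort
  for (ds in e1$cohorts) {
    tum <- rowMeans(ds$values[e1$planted, ds$labels == "tumor"])
    nor <- rowMeans(ds$values[e1$planted, ds$labels == "normal"])
    expect_equal(unname(sign(tum - nor)), unname(e1$direction),
                 tolerance = 1e-12)
  }
})

test_that("null expression (zero effect) leaves planted genes unshifted", {
  cfg <- tiny_config(seed = 6, effect_log2fc = 0)
  e <- generate_expression(cfg)
  ds <- e$cohorts[[1]]
  res <- differential_targets(ds)
  expect_false(any(res$called))
})

test_that("gene-set generator: size bounds, spiking, empty collection", {
  uni <- sprintf("SG%05d", 1:200)
  cfg <- tiny_config(seed = 3)
  coll <- generate_gene_sets(cfg, uni)
  expect_length(coll$terms, cfg$n_terms)
  sizes <- lengths(coll$terms)
  expect_true(all(sizes >= 5 & sizes <= 20))
  expect_true(all(unlist(coll$terms) %in% uni))

  empty <- generate_gene_sets(sim_config(seed = 1, n_terms = 0,
                                         term_size_range = c(5, 20)), uni)
  expect_length(empty$terms, 0L)

  spiked <- generate_gene_sets(cfg, uni, spiked = uni[1:8])
  expect_identical(spiked$terms[["SPIKED"]], sort(uni[1:8]))
})

test_that("target map covers must_include genes and is deterministic", {
  cfg <- tiny_config(seed = 12)
  comp <- paste0("c", 1:5)
  targets <- sprintf("SG%05d", 1:60)
  map <- generate_target_map(cfg, comp, targets,
                             must_include = targets[1:7])
  expect_identical(map, generate_target_map(cfg, comp, targets,
                                            must_include = targets[1:7]))
  expect_true(all(targets[1:7] %in% unlist(map)))
  expect_error(generate_target_map(cfg, comp, targets,
                                   must_include = "NOTAGENE"),
               "must_include")
})
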