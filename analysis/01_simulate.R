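#!/usr/bin/env Rscript
# Generate every synthetic input the screening pipeline consumes and write
# them as plain-text interchange files under results/synthetic/: the
# background interactome (SIF), the raw compound table (TSV), the
# compound->target map (TSV), three expression cohorts with a planted DE
# gene set (TSV + labels), a gene-set collection (GMT), and the
# configuration itself (YAML) so every later script regenerates or reloads
# the exact same inputs.

library(netpharm)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1, n_nodes = 500, edges_per_new_node = 3,
                  n_herbs = 7, compounds_per_herb = 10, whitelist_rate = 0.2,
                  n_genes = 2000, n_tumor = 20, n_normal = 20, n_cohorts = 3,
                  n_de = 50, effect_log2fc = 2, noise_sd = 1,
                  n_terms = 50, term_size_range = c(10, 50),
                  n_module = 12)
write_config(cfg, file.path(out, "config.yaml"))

net <- generate_interactome(cfg)
write_sif(net, file.path(out, "interactome.sif"))
writeLines(attr(net, "module"), file.path(out, "planted_module.txt"))

compounds <- generate_compound_table(cfg)
write_compound_table(compounds, file.path(out, "compound_table.tsv"))

# plant the high-centrality module inside the DE gene set so the drug-side
# and disease-side screens share a recoverable ground truth
genes <- sprintf("SG%05d", seq_len(cfg$n_genes))
set.seed(cfg$seed)
planted <- c(attr(net, "module"),
             sample(setdiff(genes, attr(net, "module")),
                    cfg$n_de - length(attr(net, "module"))))
expr <- generate_expression(cfg, planted = planted)
for (i in seq_along(expr$cohorts))
  write_expression(expr$cohorts[[i]],
                   file.path(out, sprintf("cohort%d.tsv", i)))
writeLines(expr$planted, file.path(out, "planted_de_genes.txt"))

collection <- generate_gene_sets(cfg, universe = syn_genes <-
                                   sprintf("SG%05d", seq_len(cfg$n_genes)))
write_gmt(collection, file.path(out, "gene_sets.gmt"))

cat(sprintf(paste0(
  "simulated: interactome %d nodes / %d edges (max degree %d, median %d),\n",
  "  %d compounds over %d herbs (%d whitelisted), %d cohorts x %d genes,\n",
  "  %d planted DE genes, %d gene sets, planted module of %d\n"),
  network_size(net)["nodes"], network_size(net)["edges"],
  max(table(c(net$edges$from, net$edges$to))),
  stats::median(table(c(net$edges$from, net$edges$to))),
  nrow(compounds), length(unique(compounds$herb)),
  sum(compounds$whitelisted), cfg$n_cohorts, cfg$n_genes,
  length(expr$planted), length(collection$terms),
  length(attr(net, "module"))))
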