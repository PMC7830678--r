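#!/usr/bin/env Rscript
# Over-representation analysis of the core targets against the synthetic
# gene-set collection: hypergeometric upper-tail test per term, BH
# adjustment, significance at q < 0.05.

library(netpharm)

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

core <- readLines("results/network/core_targets.txt")
collection <- read_gmt("results/synthetic/gene_sets.gmt",
                       universe = sprintf("SG%05d", 1:2000))

res <- enrich(core, collection, p_max = 0.05, adjust = TRUE)
utils::write.table(res, file.path(out, "core_enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("tested %d terms with overlap; %d significant at q < 0.05\n",
            nrow(res), sum(res$significant)))
if (nrow(res) > 0)
  print(utils::head(res[, c("term_id", "k", "K", "p", "q", "significant")]))
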