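#!/usr/bin/env Rscript
# Docking-energy aggregation over the packaged 7-ligand x 6-receptor
# AutoDock result matrix (kcal/mol; more negative = stronger): full pair
# ranking, best pair, and the total energy over all 42 dockings.

library(netpharm)

out <- "results/docking"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- load_docking_table()
summ <- rank_pairs(tab)

utils::write.table(summ$ranking, file.path(out, "pair_ranking.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(best_pair = summ$best_pair, total = summ$total),
                     file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

print(summ)
cat("top 5 pairs:\n")
print(utils::head(summ$ranking, 5))
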