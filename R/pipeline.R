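# End-to-end orchestration: one configuration object drives ingredient
# screening, target mapping, drug- and disease-side network expansion,
# merge-intersection, the two-stage median-centrality screen, hub selection,
# enrichment and docking ranking, with every intermediate written to disk
# and a machine-readable report returned.

#' Pipeline configuration
#'
#' Bundles the synthetic-data specification with every stage parameter of
#' the screen. All randomness derives from `sim$seed`.
#'
#' @param sim a [sim_config()]; the synthetic inputs specification.
#' @param ob_min,dl_min ingredient-screen thresholds (see
#'   [screen_ingredients()]).
#' @param alpha,lfc_min,require_concordant_sign differential-expression
#'   parameters (see [disease_targets()]).
#' @param expansion_depth seed-network expansion radius (see
#'   [expand_seed_network()]).
#' @param degree_factor,top_k,stage1_cmp,stage2_cmp topological-screen
#'   parameters (see [screen_topology()]).
#' @param p_max,adjust enrichment parameters (see [enrich()]).
#' @param docking a `docking_table`, or NULL for the packaged fixture.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(sim = sim_config(),
                            ob_min = 30, dl_min = 0.18,
                            alpha = 0.05, lfc_min = 1.0,
                            require_concordant_sign = FALSE,
                            expansion_depth = 1L,
                            degree_factor = 2, top_k = 10L,
                            stage1_cmp = "ge", stage2_cmp = "gt",
                            p_max = 0.05, adjust = TRUE,
                            docking = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  if (!is.null(docking)) stopifnot(inherits(docking, "docking_table"))
  structure(list(sim = sim, ob_min = ob_min, dl_min = dl_min,
                 alpha = alpha, lfc_min = lfc_min,
                 require_concordant_sign = require_concordant_sign,
                 expansion_depth = as.integer(expansion_depth),
                 degree_factor = degree_factor, top_k = as.integer(top_k),
                 stage1_cmp = stage1_cmp, stage2_cmp = stage2_cmp,
                 p_max = p_max, adjust = adjust, docking = docking),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full target-screening pipeline
#'
#' Stage order: ingredient screen -> compound-target mapping -> drug-side
#' network expansion -> per-cohort differential expression and intersection
#' -> disease-side network expansion -> network merge-intersection ->
#' two-stage median-centrality screen and hub selection -> enrichment of the
#' core targets -> docking-energy ranking. Identical config (including seed)
#' gives an identical report; when `out_dir` is given every intermediate is
#' written there as plain text (SIF networks, TSV tables, JSON report).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return A `pipeline_report`: per-stage counts, the candidate/disease/
#'   core/hub gene lists, the enrichment table, the docking summary, the
#'   planted ground truth of the generators, and a config echo.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim

  net <- with_stage("interactome", generate_interactome(sim))
  module <- attr(net, "module")

  candidates <- with_stage("ingredient_screen", {
    screen_ingredients(generate_compound_table(sim),
                       ob_min = config$ob_min, dl_min = config$dl_min)
  })
  if (nrow(candidates) == 0L)
    stop("pipeline stage 'ingredient_screen' failed: no candidate survived",
         call. = FALSE)

  bip <- with_stage("bipartite", {
    map <- generate_target_map(sim, candidates$compound, net$nodes,
                               must_include = module)
    build_bipartite(candidates, map)
  })

  drug_net <- with_stage("drug_network",
    expand_seed_network(bip$targets, net, depth = config$expansion_depth))

  expr <- with_stage("expression", {
    genes <- syn_genes(sim$n_genes)
    planted <- NULL
    if (length(module) > 0L) {
      if (!all(module %in% genes) || sim$n_de < length(module))
        stop("planted module must fit inside the DE gene namespace")
      set.seed(derive_seed(sim$seed, "planted"))
      planted <- c(module, sample(setdiff(genes, module),
                                  sim$n_de - length(module)))
    }
    generate_expression(sim, planted = planted)
  })

  dis <- with_stage("disease_targets",
    disease_targets(expr$cohorts, alpha = config$alpha,
                    lfc_min = config$lfc_min,
                    require_concordant_sign = config$require_concordant_sign))

  disease_net <- with_stage("disease_network",
    expand_seed_network(dis$targets, net, depth = config$expansion_depth))

  merged <- with_stage("intersection", intersect_networks(drug_net,
                                                          disease_net))

  screen <- with_stage("topology_screen",
    screen_topology(merged, degree_factor = config$degree_factor,
                    k = config$top_k, stage1_cmp = config$stage1_cmp,
                    stage2_cmp = config$stage2_cmp))

  enrichment <- with_stage("enrichment", {
    collection <- generate_gene_sets(sim, universe = syn_genes(sim$n_genes))
    enrich(screen$core, collection, p_max = config$p_max,
           adjust = config$adjust)
  })

  docking <- with_stage("docking_rank", {
    tab <- if (is.null(config$docking)) load_docking_table()
           else config$docking
    rank_pairs(tab)
  })

  counts <- list(
    compounds = nrow(candidates),
    putative_targets = length(bip$targets),
    drug_network = as.list(network_size(drug_net)),
    disease_targets = length(dis$targets),
    disease_network = as.list(network_size(disease_net)),
    merged = as.list(network_size(merged)),
    stage1 = as.list(network_size(screen$stage1)),
    core = length(screen$core),
    hubs = length(screen$hubs),
    enriched_terms = sum(enrichment$significant))

  report <- structure(list(
    counts = counts,
    candidates = candidates,
    bipartite = bip,
    disease = dis$targets,
    screen = screen,
    core = screen$core,
    hubs = screen$hubs,
    enrichment = enrichment,
    docking = docking,
    truth = list(module = module, planted_de = expr$planted),
    config = config), class = "pipeline_report")

  if (!is.null(out_dir)) write_report(report, out_dir, drug_net,
                                      disease_net, merged)
  report
}

write_report <- function(report, out_dir, drug_net, disease_net, merged) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(report$candidates, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$bipartite$links, p("bipartite.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sif(drug_net, p("drug_network.sif"))
  write_sif(disease_net, p("disease_network.sif"))
  write_sif(merged, p("merged_network.sif"))
  write_sif(report$screen$stage1, p("stage1_network.sif"))
  write_sif(report$screen$stage2_network, p("core_network.sif"))
  writeLines(report$disease, p("disease_targets.txt"))
  writeLines(report$core, p("core_targets.txt"))
  writeLines(report$hubs, p("hub_targets.txt"))
  utils::write.table(report$enrichment, p("enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$docking$ranking, p("docking_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(counts = report$counts,
         hubs = report$hubs,
         best_docking_pair = report$docking$best_pair,
         docking_total = report$docking$total),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cn <- x$counts
  cat("pipeline_report\n",
      sprintf("  candidates: %d, putative targets: %d\n", cn$compounds,
              cn$putative_targets),
      sprintf("  drug net %d/%d, disease targets %d, disease net %d/%d\n",
              cn$drug_network$nodes, cn$drug_network$edges,
              cn$disease_targets, cn$disease_network$nodes,
              cn$disease_network$edges),
      sprintf("  merged %d/%d -> stage1 %d/%d -> core %d -> hubs %d\n",
              cn$merged$nodes, cn$merged$edges, cn$stage1$nodes,
              cn$stage1$edges, cn$core, cn$hubs),
      sprintf("  significant terms: %d; best docking %.2f kcal/mol\n",
              cn$enriched_terms, x$docking$best_pair$energy), sep = "")
  invisible(x)
}
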