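# Fixed-seed synthetic generators for every input the screening pipeline
# consumes: a scale-free interactome, a compound table with ADME scores, a
# compound->target map, multi-cohort expression data with planted
# differential expression, and gene-set collections. One integer seed drives
# everything; each generator derives its own sub-stream from (seed, name) so
# adding a call never perturbs the others.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with validation.
#' Defaults describe the study conditions the pipeline is evaluated under:
#' a 500-node scale-free interactome (3 edges per new node), 7 herbs x 10
#' compounds, and three expression cohorts of 20 tumor vs 20 normal samples
#' over 2000 genes with 50 planted differentially expressed genes at
#' |log2FC| = 2 and unit noise.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_nodes interactome size (>= 2).
#' @param edges_per_new_node preferential-attachment edges added per new node
#'   (>= 1 and < `n_nodes`).
#' @param n_herbs,compounds_per_herb compound-table dimensions.
#' @param whitelist_rate probability a compound carries the literature
#'   whitelist flag, in `[0, 1]`.
#' @param n_genes expression gene-namespace size.
#' @param n_tumor,n_normal per-cohort group sizes.
#' @param n_cohorts number of expression cohorts (default 3).
#' @param n_de number of planted differentially expressed genes
#'   (< `n_genes`).
#' @param effect_log2fc planted log2 fold-change magnitude.
#' @param noise_sd standard deviation of additive log2-scale noise.
#' @param n_terms number of gene sets to generate.
#' @param term_size_range length-2 integer vector, min/max genes per set.
#' @param n_module size of an optional planted high-centrality module in the
#'   interactome (0 = none): the `n_module` highest-degree nodes are wired
#'   into a clique and reported as ground truth.
#' @param targets_per_compound mean number of targets mapped per compound.
#' @return A validated `sim_config` (named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_nodes = 50)
#' @export
sim_config <- function(seed = 1L,
                       n_nodes = 500L, edges_per_new_node = 3L,
                       n_herbs = 7L, compounds_per_herb = 10L,
                       whitelist_rate = 0.2,
                       n_genes = 2000L, n_tumor = 20L, n_normal = 20L,
                       n_cohorts = 3L, n_de = 50L,
                       effect_log2fc = 2, noise_sd = 1,
                       n_terms = 50L, term_size_range = c(10L, 50L),
                       n_module = 0L, targets_per_compound = 8L) {
  cfg <- list(seed = as.integer(seed),
              n_nodes = as.integer(n_nodes),
              edges_per_new_node = as.integer(edges_per_new_node),
              n_herbs = as.integer(n_herbs),
              compounds_per_herb = as.integer(compounds_per_herb),
              whitelist_rate = as.numeric(whitelist_rate),
              n_genes = as.integer(n_genes),
              n_tumor = as.integer(n_tumor),
              n_normal = as.integer(n_normal),
              n_cohorts = as.integer(n_cohorts),
              n_de = as.integer(n_de),
              effect_log2fc = as.numeric(effect_log2fc),
              noise_sd = as.numeric(noise_sd),
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_module = as.integer(n_module),
              targets_per_compound = as.integer(targets_per_compound))
  counts <- c("n_nodes", "edges_per_new_node", "n_herbs",
              "compounds_per_herb", "n_genes", "n_tumor", "n_normal",
              "n_cohorts", "n_de", "n_terms", "n_module",
              "targets_per_compound")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("configuration error: '", f, "' must be a non-negative count")
  if (cfg$n_nodes < 2L)
    stop("configuration error: 'n_nodes' must be >= 2")
  if (cfg$edges_per_new_node < 1L || cfg$edges_per_new_node >= cfg$n_nodes)
    stop("configuration error: 'edges_per_new_node' must be >= 1 and < n_nodes")
  if (cfg$whitelist_rate < 0 || cfg$whitelist_rate > 1)
    stop("configuration error: 'whitelist_rate' must be in [0, 1]")
  if (cfg$n_de >= cfg$n_genes)
    stop("configuration error: 'n_de' must be < n_genes")
  if (cfg$noise_sd < 0)
    stop("configuration error: 'noise_sd' must be >= 0")
  if (length(cfg$term_size_range) != 2L ||
      cfg$term_size_range[1L] > cfg$term_size_range[2L] ||
      cfg$term_size_range[1L] < 1L)
    stop("configuration error: 'term_size_range' must be (min, max), min >= 1")
  if (cfg$n_module > cfg$n_nodes)
    stop("configuration error: 'n_module' must be <= n_nodes")
  structure(cfg, class = c("sim_config", "list"))
}

# Deterministic sub-stream seed from (seed, call-name); stays below 2^31.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  (as.integer(seed) %% 20000L) * 100000L + as.integer(h)
}

# Synthetic gene-symbol namespace shared by the interactome and the
# expression cohorts.
syn_genes <- function(n) sprintf("SG%05d", seq_len(n))

#' Generate a scale-free synthetic interactome
#'
#' Grows an undirected simple connected graph by preferential attachment
#' (Barabasi-Albert scheme, via `igraph::sample_pa`), mimicking the heavy-
#' tailed degree distribution of protein-protein interaction networks that
#' the median-centrality filters exploit. Node labels come from a synthetic
#' gene-symbol namespace shared with [generate_expression()].
#'
#' If `config$n_module > 0`, the `n_module` highest-degree nodes are
#' additionally wired into a clique; their labels are returned in the
#' `"module"` attribute as planted high-centrality ground truth.
#'
#' @param config a [sim_config()].
#' @return An `interactome`; attribute `"module"` holds the planted module
#'   labels (character(0) when none).
#' @export
generate_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "interactome"))
  g <- igraph::sample_pa(config$n_nodes, m = config$edges_per_new_node,
                         directed = FALSE)
  labels <- syn_genes(config$n_nodes)
  igraph::V(g)$name <- labels
  net <- from_igraph(g)
  module <- character(0)
  if (config$n_module > 0L) {
    deg <- igraph::degree(g)
    module <- labels[order(deg, decreasing = TRUE)[seq_len(config$n_module)]]
    if (length(module) > 1L) {
      pairs <- t(utils::combn(sort(module), 2L))
      net <- interactome(rbind(as.matrix(net$edges), pairs),
                         nodes = net$nodes)
    }
  }
  attr(net, "module") <- module
  net
}

#' Generate a synthetic compound table
#'
#' Emulates a raw herbal-compound database extract: `n_herbs` herbs with
#' `compounds_per_herb` compounds each. Oral bioavailability (OB, %) is
#' uniform on (0, 100) and drug-likeness (DL) uniform on (0, 1), so both ADME
#' thresholds (30% and 0.18) are exercised on both sides. Each record is
#' independently whitelisted with probability `whitelist_rate`.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns herb, compound, ob, dl, whitelisted.
#' @export
generate_compound_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_herbs < 1L || config$compounds_per_herb < 1L)
    stop("configuration error: 'n_herbs' and 'compounds_per_herb' must be >= 1")
  set.seed(derive_seed(config$seed, "compounds"))
  herbs <- sprintf("HERB%02d", seq_len(config$n_herbs))
  n <- config$n_herbs * config$compounds_per_herb
  herb <- rep(herbs, each = config$compounds_per_herb)
  data.frame(
    herb = herb,
    compound = paste0(herb, "_C", rep(seq_len(config$compounds_per_herb),
                                      times = config$n_herbs)),
    ob = stats::runif(n, 0, 100),
    dl = stats::runif(n, 0, 1),
    whitelisted = stats::runif(n) < config$whitelist_rate,
    stringsAsFactors = FALSE)
}

#' Construct an expression dataset
#'
#' @param values numeric genes x samples matrix of log2 expression with gene
#'   symbols as rownames and sample ids as colnames.
#' @param labels named character vector (or vector aligned with columns) of
#'   group labels, each `"tumor"` or `"normal"`.
#' @return An `expression_dataset`: list(genes, samples, values, labels).
#' @export
expression_dataset <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (!is.null(names(labels))) labels <- labels[colnames(values)]
  labels <- as.character(labels)
  if (length(labels) != ncol(values) || anyNA(labels))
    stop("labels must cover every sample")
  if (!all(labels %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  if (anyNA(values)) stop("expression values must not contain NA")
  if (min(table(factor(labels, c("tumor", "normal")))) < 2L)
    stop("both groups need >= 2 samples")
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d tumor, %d normal)\n",
              length(x$genes), length(x$samples),
              sum(x$labels == "tumor"), sum(x$labels == "normal")))
  invisible(x)
}

#' Generate multi-cohort expression data with planted signal
#'
#' Emulates several case/control expression cohorts sharing one planted set
#' of differentially expressed genes: every cohort draws independent
#' N(0, noise_sd^2) log2 noise, and in tumor samples the planted genes are
#' shifted by +/- `effect_log2fc` (sign fixed per gene, identical across
#' cohorts). The planted gene list is returned explicitly for truth-tracking,
#' never inferred downstream.
#'
#' @param config a [sim_config()].
#' @param planted optional character vector of genes to plant; defaults to a
#'   random draw of `config$n_de` genes from the namespace. Must lie inside
#'   the gene namespace.
#' @return list with elements `cohorts` (list of `expression_dataset`),
#'   `planted` (character) and `direction` (named +/-1 per planted gene).
#' @export
generate_expression <- function(config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tumor < 2L || config$n_normal < 2L)
    stop("configuration error: group sizes must be >= 2")
  genes <- syn_genes(config$n_genes)
  set.seed(derive_seed(config$seed, "expression"))
  if (is.null(planted)) {
    planted <- sort(sample(genes, config$n_de))
  } else {
    planted <- sort(unique(toupper(as.character(planted))))
    if (!all(planted %in% genes))
      stop("planted genes must belong to the synthetic gene namespace")
  }
  direction <- stats::setNames(sample(c(-1, 1), length(planted),
                                      replace = TRUE), planted)
  n_samp <- config$n_tumor + config$n_normal
  labels <- c(rep("tumor", config$n_tumor), rep("normal", config$n_normal))
  cohorts <- lapply(seq_len(config$n_cohorts), function(i) {
    m <- matrix(stats::rnorm(config$n_genes * n_samp, 0, config$noise_sd),
                nrow = config$n_genes,
                dimnames = list(genes, sprintf("C%d_S%02d", i,
                                               seq_len(n_samp))))
    m[planted, labels == "tumor"] <-
      m[planted, labels == "tumor"] + direction * config$effect_log2fc
    expression_dataset(m, labels)
  })
  list(cohorts = cohorts, planted = planted, direction = direction)
}

#' Construct a gene-set collection
#'
#' @param terms named list of character vectors (term id -> member genes).
#' @param description optional named character vector of term descriptions;
#'   defaults to the term ids.
#' @param universe background gene set; defaults to the union of all members.
#'   Members are restricted to the universe.
#' @return A `gene_set_collection`: list(terms, description, universe).
#' @export
gene_set_collection <- function(terms, description = NULL, universe = NULL) {
  if (is.null(names(terms)) && length(terms) > 0L)
    stop("terms must be a named list")
  if (anyDuplicated(names(terms)))
    stop("term ids must be unique")
  terms <- lapply(terms, function(g) sort(unique(toupper(as.character(g)))))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- sort(unique(toupper(as.character(universe))))
    terms <- lapply(terms, intersect, y = universe)
  }
  if (is.null(description)) description <- stats::setNames(names(terms),
                                                           names(terms))
  structure(list(terms = terms,
                 description = description[names(terms)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms over a universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}

#' Generate a synthetic gene-set collection
#'
#' Samples `n_terms` sets uniformly without replacement from `universe`, with
#' sizes uniform over `term_size_range`. An optional spiked term equal to a
#' caller-supplied gene list is appended under id `"SPIKED"`, for enrichment
#' power tests.
#'
#' @param config a [sim_config()].
#' @param universe character vector of background genes.
#' @param spiked optional character vector; added verbatim as term "SPIKED".
#' @return A `gene_set_collection` with `universe` as background.
#' @export
generate_gene_sets <- function(config, universe, spiked = NULL) {
  stopifnot(inherits(config, "sim_config"))
  universe <- unique(toupper(as.character(universe)))
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (config$term_size_range[2L] > length(universe))
    stop("configuration error: term sizes exceed the universe")
  set.seed(derive_seed(config$seed, "genesets"))
  sizes <- if (config$n_terms > 0L)
    sample(seq(config$term_size_range[1L], config$term_size_range[2L]),
           config$n_terms, replace = TRUE) else integer(0)
  terms <- lapply(sizes, function(s) sample(universe, s))
  names(terms) <- sprintf("T%04d", seq_len(config$n_terms))
  if (!is.null(spiked)) terms[["SPIKED"]] <- toupper(as.character(spiked))
  gene_set_collection(terms, universe = universe)
}

#' Generate a synthetic compound-to-target map
#'
#' Assigns each compound a random draw of protein targets from `targets`
#' (size `config$targets_per_compound`, at least 1). Genes listed in
#' `must_include` are guaranteed coverage by spreading them round-robin over
#' the compounds, so a planted module is always reachable from the drug side.
#'
#' @param config a [sim_config()].
#' @param compounds character vector of compound names.
#' @param targets character vector of candidate target symbols.
#' @param must_include optional character vector of targets that every map
#'   must cover (each assigned to at least one compound).
#' @return named list compound -> character vector of target symbols.
#' @export
generate_target_map <- function(config, compounds, targets,
                                must_include = NULL) {
  stopifnot(inherits(config, "sim_config"))
  compounds <- as.character(compounds)
  targets <- unique(toupper(as.character(targets)))
  if (length(compounds) == 0L || length(targets) == 0L)
    stop("compounds and targets must be non-empty")
  set.seed(derive_seed(config$seed, "targetmap"))
  k <- max(1L, min(config$targets_per_compound, length(targets)))
  map <- lapply(compounds, function(cp) sample(targets, k))
  names(map) <- compounds
  if (!is.null(must_include)) {
    must_include <- unique(toupper(as.character(must_include)))
    if (!all(must_include %in% targets))
      stop("must_include genes must be among the candidate targets")
    idx <- rep(seq_along(compounds), length.out = length(must_include))
    for (i in seq_along(must_include))
      map[[idx[i]]] <- union(map[[idx[i]]], must_include[i])
  }
  lapply(map, sort)
}
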