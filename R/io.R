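# Readers/writers for the plain-text interchange formats the pipeline uses:
# SIF and 2-column TSV edge lists (Cytoscape interchange), GMT gene sets,
# TSV expression matrices with a companion label file, YAML/JSON configs.

#' Write an interactome as SIF
#'
#' Simple interaction format: three tab-separated columns
#' (node, interaction type, node). Isolated nodes are written as single-column
#' rows, the convention Cytoscape uses for orphan nodes.
#'
#' @param g an `interactome`.
#' @param path output file path.
#' @param interaction interaction keyword, default `"pp"`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path, interaction = "pp") {
  stopifnot(inherits(g, "interactome"))
  lines <- character(0)
  if (nrow(g$edges) > 0L)
    lines <- paste(g$edges$from, interaction, g$edges$to, sep = "\t")
  iso <- setdiff(g$nodes, c(g$edges$from, g$edges$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read an interactome from SIF
#'
#' @param path SIF file path.
#' @return An `interactome`.
#' @export
read_sif <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf == 2L) || any(nf > 3L))
    stop("malformed SIF line (expected 1 or 3 fields): ",
         raw[which(nf == 2L | nf > 3L)[1L]])
  ed <- do.call(rbind, lapply(parts[nf == 3L],
                              function(p) c(p[[1L]], p[[3L]])))
  iso <- unlist(parts[nf == 1L])
  interactome(ed, nodes = iso)
}

#' Write an interactome as a two-column TSV edge list
#'
#' Isolated nodes cannot be represented in a bare edge list and are dropped
#' with a warning.
#'
#' @param g an `interactome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(g, path) {
  stopifnot(inherits(g, "interactome"))
  iso <- setdiff(g$nodes, c(g$edges$from, g$edges$to))
  if (length(iso) > 0L)
    warning(length(iso), " isolated node(s) not representable in an edge list")
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an interactome from a two-column TSV edge list
#'
#' @param path TSV file with header and columns `from`, `to`.
#' @return An `interactome`.
#' @export
read_edges <- function(path) {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE)
  interactome(ed)
}

#' Write a gene-set collection as GMT
#'
#' One tab-separated line per term: term id, description, member genes.
#'
#' @param collection a `gene_set_collection` (see [gene_set_collection()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- names(collection$terms)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$description[[id]], collection$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' @param path GMT file path.
#' @param universe optional background gene set; defaults to the union of all
#'   term members.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line (need id, description, >=1 gene): line ",
         which(bad)[1L])
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  terms <- lapply(parts, function(p) p[-(1:2)])
  names(terms) <- ids
  names(desc) <- ids
  gene_set_collection(terms, description = desc, universe = universe)
}

#' Write an expression dataset as TSV
#'
#' Writes the log2 expression matrix (genes x samples, header row of sample
#' ids, first column `gene`) and a companion two-column label file
#' (`sample`, `label`).
#'
#' @param dataset an `expression_dataset`.
#' @param path matrix output path.
#' @param labels_path label-file output path; default appends `.labels.tsv`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path,
                             labels_path = paste0(path, ".labels.tsv")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene = dataset$genes, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = dataset$samples, label = dataset$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression dataset from TSV
#'
#' @param path matrix file written by [write_expression()].
#' @param labels_path companion label file path.
#' @return An `expression_dataset`.
#' @export
read_expression <- function(path, labels_path = paste0(path, ".labels.tsv")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$gene
  expression_dataset(values, labels = stats::setNames(lab$label, lab$sample))
}

#' Write a compound table as TSV
#'
#' @param table data.frame with columns herb, compound, ob, dl, whitelisted.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound table from TSV
#'
#' @param path TSV with header herb, compound, ob, dl, whitelisted.
#' @return data.frame of compound records.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$whitelisted <- as.logical(df$whitelisted)
  validate_compound_table(df)
  df
}

#' Write a simulation or pipeline configuration as YAML
#'
#' @param config a named list (e.g. from [sim_config()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#'
#' @param path YAML file path.
#' @return A `sim_config` object (validated).
#' @export
read_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
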