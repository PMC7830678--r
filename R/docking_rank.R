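# Aggregation and ranking of a precomputed ligand x receptor docking-energy
# matrix (kcal/mol, more negative = stronger binding). The docking engine
# itself is out of scope; this module consumes its per-pair best energies.

#' Construct a docking-energy table
#'
#' @param energies numeric ligand x receptor matrix of binding energies in
#'   kcal/mol, with ligand rownames and receptor colnames. Every cell must be
#'   present and finite.
#' @return A `docking_table`: list(ligands, receptors, energies).
#' @export
docking_table <- function(energies) {
  energies <- as.matrix(energies)
  if (is.null(rownames(energies)) || is.null(colnames(energies)))
    stop("energies must have ligand rownames and receptor colnames")
  bad <- which(!is.finite(energies), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("missing or non-finite energy at (",
         rownames(energies)[bad[1L, 1L]], ", ",
         colnames(energies)[bad[1L, 2L]], ")")
  structure(list(ligands = rownames(energies),
                 receptors = colnames(energies),
                 energies = energies),
            class = "docking_table")
}

#' Read a docking-energy matrix from TSV
#'
#' Expects a header row of receptor names and a first column of ligand
#' names.
#'
#' @param path TSV file path.
#' @return A `docking_table`.
#' @export
read_docking_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  docking_table(m)
}

#' Load the packaged docking-energy fixture
#'
#' A transcription of a published 7-ligand x 6-receptor AutoDock result
#' matrix (kcal/mol): seven phytochemicals from the two monarch herbs of a
#' classic decoction docked against the six hub targets EGFR, CUL3, APP,
#' MCM2, CDK2 and FN1. Note the source's own text and table disagree on
#' which ligand scores -7.44 against MCM2 (senkyunolide G vs ferulic acid);
#' this transcription follows the printed table, which assigns it to ferulic
#' acid.
#'
#' @return A `docking_table`.
#' @export
load_docking_table <- function() {
  read_docking_matrix(system.file("extdata", "docking_energies.tsv",
                                  package = "netpharm", mustWork = TRUE))
}

#' Rank all ligand-receptor docking pairs
#'
#' Sorts all cells ascending by energy (most negative = strongest binding
#' first; ties broken lexicographically by ligand then receptor) and sums the
#' whole matrix.
#'
#' @param table a `docking_table`.
#' @return A `docking_summary`: list with `best_pair` (one-row data.frame
#'   ligand/receptor/energy), `ranking` (all pairs, sorted), and `total`
#'   (sum over all cells, kcal/mol).
#' @export
rank_pairs <- function(table) {
  stopifnot(inherits(table, "docking_table"))
  ranking <- expand.grid(ligand = table$ligands,
                         receptor = table$receptors,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ranking$energy <- as.vector(table$energies)
  ranking <- ranking[order(ranking$energy, ranking$ligand,
                           ranking$receptor), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(best_pair = ranking[1L, , drop = FALSE],
                 ranking = ranking,
                 total = sum(table$energies)),
            class = "docking_summary")
}

#' @export
print.docking_summary <- function(x, ...) {
  cat(sprintf("docking_summary: %d pairs; best %s x %s at %.2f kcal/mol; total %.2f kcal/mol\n",
              nrow(x$ranking), x$best_pair$ligand, x$best_pair$receptor,
              x$best_pair$energy, x$total))
  invisible(x)
}
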