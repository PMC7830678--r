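# Disease-side target calling: per-cohort differential expression on
# case/control log2 matrices, then intersection across cohorts, mirroring the
# common multi-cohort "Venn" strategy for deriving disease-related targets.

#' Per-gene differential expression (Welch t-test, BH FDR)
#'
#' For each gene, a Welch two-sample t-test of tumor vs normal log2 values;
#' log2 fold-change is mean(tumor) - mean(normal). P-values are
#' Benjamini-Hochberg adjusted over all genes of the dataset, and a gene is
#' called when `q < alpha` and `|log2fc| >= lfc_min`.
#'
#' Degenerate genes are kept, not dropped: when both group variances are zero
#' the p-value is 1 if the group means are equal and 0 otherwise (forced
#' separation).
#'
#' @param dataset an [expression_dataset()].
#' @param alpha FDR level for calling; default 0.05.
#' @param lfc_min minimum absolute log2 fold-change for calling; default 1.
#' @return data.frame with columns gene, log2fc, p, q, called, ordered as the
#'   dataset's genes.
#' @export
differential_targets <- function(dataset, alpha = 0.05, lfc_min = 1.0) {
  stopifnot(inherits(dataset, "expression_dataset"))
  tum <- dataset$values[, dataset$labels == "tumor", drop = FALSE]
  nor <- dataset$values[, dataset$labels == "normal", drop = FALSE]
  n1 <- ncol(tum); n2 <- ncol(nor)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(tum); m2 <- rowMeans(nor)
  v1 <- rowSums((tum - m1)^2) / (n1 - 1L)
  v2 <- rowSums((nor - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate))
    p[degenerate] <- ifelse(abs(lfc[degenerate]) > 0, 0, 1)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = dataset$genes, log2fc = lfc, p = p, q = q,
             called = q < alpha & abs(lfc) >= lfc_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect gene sets
#'
#' @param sets non-empty list of character vectors.
#' @return character vector: genes present in every set (sorted).
#' @examples
#' intersect_sets(list(c("A", "B", "C"), c("B", "C", "D"), c("C", "B", "E")))
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("need a non-empty list of gene sets")
  out <- Reduce(intersect, lapply(sets, function(s)
    unique(toupper(as.character(s)))))
  sort(out)
}

#' Disease-related targets from multiple cohorts
#'
#' Runs [differential_targets()] on every cohort and intersects the called
#' gene sets. By default direction is ignored at intersection time (a gene up
#' in one cohort and down in another still intersects);
#' `require_concordant_sign = TRUE` additionally demands the same
#' fold-change sign in every cohort.
#'
#' @param cohorts list of [expression_dataset()] objects.
#' @param alpha,lfc_min passed to [differential_targets()].
#' @param require_concordant_sign logical; default FALSE.
#' @return list with `targets` (intersected gene vector) and `per_cohort`
#'   (list of per-cohort result data.frames).
#' @export
disease_targets <- function(cohorts, alpha = 0.05, lfc_min = 1.0,
                            require_concordant_sign = FALSE) {
  if (length(cohorts) == 0L) stop("need >= 1 cohort")
  res <- lapply(cohorts, differential_targets, alpha = alpha,
                lfc_min = lfc_min)
  called <- lapply(res, function(r) r$gene[r$called])
  targets <- intersect_sets(called)
  if (require_concordant_sign && length(targets) > 0L) {
    signs <- vapply(res, function(r)
      sign(r$log2fc[match(targets, r$gene)]), numeric(length(targets)))
    signs <- matrix(signs, nrow = length(targets))
    concordant <- apply(signs, 1L, function(s) all(s == s[1L]))
    targets <- targets[concordant]
  }
  list(targets = targets, per_cohort = res)
}
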