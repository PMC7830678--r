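# Over-representation analysis of a query gene set against a gene-set
# collection: hypergeometric upper-tail test per term, BH multiplicity
# control, a stand-in for DAVID/ClueGO-style functional enrichment.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` belong to the term, the probability of an
#' overlap at least `k`. Evaluated through the distribution function in
#' log-space (`stats::phyper`) for numerical stability.
#'
#' @param k observed overlap, `0 <= k <= min(K, n)`.
#' @param K term size in the universe.
#' @param n query size in the universe.
#' @param N universe size.
#' @return Probability in `[0, 1]`; exactly 1 when `k = 0`.
#' @examples
#' hypergeometric_p(5, 5, 5, 10)  # 1/choose(10, 5) = 1/252
#' @export
hypergeometric_p <- function(k, K, n, N) {
  if (any(is.na(c(k, K, n, N)))) stop("arguments must not be NA")
  if (K < 0 || K > N || n < 0 || n > N)
    stop("need 0 <= K <= N and 0 <= n <= N")
  if (k < 0 || k > min(K, n))
    stop("need 0 <= k <= min(K, n)")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Over-representation analysis against a gene-set collection
#'
#' Restricts the query to the collection's universe (dropped genes are
#' reported via a message), tests every term with overlap k >= 1 by
#' [hypergeometric_p()], BH-adjusts across all tested terms, and flags rows
#' with adjusted q (or raw p when `adjust = FALSE`) below `p_max`. The full
#' table is returned regardless of significance, sorted ascending by p
#' (ties by term id).
#'
#' @param query character vector of gene symbols.
#' @param collection a [gene_set_collection()].
#' @param p_max significance threshold; default 0.05.
#' @param adjust flag significance on BH-adjusted q (default) or on raw p,
#'   the behaviour of the classical enrichment web tools.
#' @return data.frame with columns term_id, description, k, K, n, N, p, q,
#'   significant.
#' @export
enrich <- function(query, collection, p_max = 0.05, adjust = TRUE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  if (length(universe) == 0L) stop("collection universe is empty")
  query <- unique(toupper(as.character(query)))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0L)
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$terms), function(id) {
    members <- collection$terms[[id]]
    k <- length(intersect(query, members))
    if (k < 1L) return(NULL)
    K <- length(members)
    data.frame(term_id = id,
               description = unname(collection$description[[id]]),
               k = k, K = K, n = n, N = N,
               p = hypergeometric_p(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(
    term_id = character(0), description = character(0),
    k = integer(0), K = integer(0), n = integer(0), N = integer(0),
    p = numeric(0), stringsAsFactors = FALSE)), rows))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- (if (adjust) out$q else out$p) < p_max
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
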