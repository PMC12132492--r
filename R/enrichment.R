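#' Hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` query genes
#' from a universe of `N` containing `K` members of the pathway, the chance
#' of an overlap at least as large as the observed `k`. Exact tail
#' summation.
#'
#' @param k Observed overlap ("counts").
#' @param K Pathway size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stopf("inconsistent counts: k=%d K=%d n=%d N=%d", k, K, n, N)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis against a gene-set collection
#'
#' Intersects the query and every collection set with the universe (genes
#' outside the universe are dropped and counted), tests each set with
#' [hypergeometric_test()], adjusts with BH across the collection's rows,
#' and sorts by p.
#'
#' @param query `GeneSignature`.
#' @param collection List of `GeneSignature`s (e.g. from
#'   [read_gene_sets()]).
#' @param universe Character vector of background gene ids (typically all
#'   genes expressed in the relevant matrix).
#' @return `data.frame` (one row per set): set, k, K, n, N, p, p_adj;
#'   attribute `"dropped_query"` counts query genes outside the universe.
#' @export
overrepresentation <- function(query, collection, universe) {
  universe <- unique(universe)
  q <- intersect(query$genes, universe)
  dropped <- length(query$genes) - length(q)
  if (length(q) == 0) stopf("query shares no gene with the universe")
  N <- length(universe)
  n <- length(q)
  rows <- lapply(collection, function(s) {
    set_u <- intersect(s$genes, universe)
    K <- length(set_u)
    k <- length(intersect(set_u, q))
    data.frame(set = s$name, k = k, K = K, n = n, N = N,
               p = if (K == 0) 1 else hypergeometric_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_query") <- dropped
  res
}
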