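#' Ranked gene list
#'
#' Ordered differential-expression records sorted descending by log2
#' fold-change, ties broken by ascending p then gene id, so two runs on the
#' same values always produce the same order.
#'
#' @param gene_id Character vector, unique.
#' @param log2fc Numeric scores.
#' @param p Raw p-values in `[0,1]`.
#' @param p_adj Adjusted p-values, `p_adj >= p` elementwise.
#' @param resort Re-sort by the tie-break rule (default TRUE).
#' @return A `RankedGeneList` (a data.frame subclass).
#' @export
ranked_gene_list <- function(gene_id, log2fc, p = rep(NA_real_, length(gene_id)),
                             p_adj = p, resort = TRUE) {
  if (anyDuplicated(gene_id)) stopf("gene ids are not unique in ranked list")
  df <- data.frame(gene_id = as.character(gene_id), log2fc = log2fc,
                   p = p, p_adj = p_adj, stringsAsFactors = FALSE)
  if (any(stats::na.omit(df$p_adj < df$p)))
    stopf("p_adj must be >= p")
  if (resort) df <- df[order(-df$log2fc, df$p, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("RankedGeneList", "data.frame")
  df
}

#' Named gene set
#'
#' @param name Set name.
#' @param genes Character vector of member gene ids (deduplicated).
#' @param direction `"up"`, `"down"` or `"unsigned"`.
#' @return A `GeneSignature`.
#' @export
gene_signature <- function(name, genes, direction = c("up", "down", "unsigned")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (length(genes) == 0) stopf("gene signature '%s' is empty", name)
  structure(list(name = name, genes = genes, direction = direction),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s' (%s): %d genes\n",
              x$name, x$direction, length(x$genes)))
  invisible(x)
}

#' Per-gene Wilcoxon differential expression between two cell groups
#'
#' For each gene: two-sided Wilcoxon rank-sum p of group A versus group B on
#' log-normalized values; log2 fold-change computed on de-logged group means
#' with a pseudocount; Bonferroni adjustment over tested genes (the
#' single-cell marker-test convention; `adjust = "BH"` available). Genes
#' whose values are identical across both groups get p = 1.
#'
#' @param m `ExpressionMatrix`, lognorm layer.
#' @param group_a,group_b Disjoint cell-id vectors, each of size >= 3.
#' @param pseudocount Added to de-logged means before the ratio (default 1).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return A `RankedGeneList` over all genes, unfiltered.
#' @export
differential_expression <- function(m, group_a, group_b, pseudocount = 1,
                                    adjust = c("bonferroni", "BH")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  adjust <- match.arg(adjust)
  if (m$layer != "lognorm") stopf("differential_expression expects lognorm layer")
  if (length(intersect(group_a, group_b)) > 0) stopf("groups overlap")
  if (length(group_a) < 3 || length(group_b) < 3)
    stopf("each group needs >= 3 cells")
  xa <- as.matrix(m$values[, match(group_a, colnames(m$values)), drop = FALSE])
  xb <- as.matrix(m$values[, match(group_b, colnames(m$values)), drop = FALSE])
  base <- (m$norm$log_base %||% exp(1))
  delog <- function(x) base^x - 1
  mean_a <- rowMeans(delog(xa))
  mean_b <- rowMeans(delog(xb))
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  n_gene <- nrow(xa)
  pvals <- vapply(seq_len(n_gene), function(i) {
    a <- xa[i, ]; b <- xb[i, ]
    if (max(c(a, b)) == min(c(a, b))) return(1)
    wilcoxon_rank_sum(a, b, "two_sided")$p
  }, numeric(1))
  if (any(pvals == 1 & lfc == 0))
    invisible(NULL) # degenerate genes handled above
  p_adj <- if (adjust == "bonferroni") pmin(pvals * n_gene, 1)
           else stats::p.adjust(pvals, "BH")
  ranked_gene_list(rownames(xa), lfc, pvals, p_adj)
}

#' Keep upregulated, significant entries of a ranked list
#'
#' Strict inequalities on both thresholds (`log2fc > min_lfc`,
#' `p_adj < max_padj`); order is preserved.
#'
#' @param rl `RankedGeneList`.
#' @param min_lfc Lower bound on log2 fold-change (default 0, exclusive).
#' @param max_padj Upper bound on adjusted p (default 0.05, exclusive).
#' @return Filtered `RankedGeneList`.
#' @export
filter_up <- function(rl, min_lfc = 0, max_padj = 0.05) {
  keep <- rl$log2fc > min_lfc & rl$p_adj < max_padj
  out <- rl[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedGeneList", "data.frame")
  out
}

#' Keep downregulated, significant entries of a ranked list
#'
#' Mirror of [filter_up()]: `log2fc < max_lfc` (default 0) and
#' `p_adj < max_padj`, both strict.
#'
#' @param rl `RankedGeneList`.
#' @param max_lfc Upper bound on log2 fold-change (default 0, exclusive).
#' @param max_padj Upper bound on adjusted p (default 0.05, exclusive).
#' @return Filtered `RankedGeneList`.
#' @export
filter_down <- function(rl, max_lfc = 0, max_padj = 0.05) {
  keep <- rl$log2fc < max_lfc & rl$p_adj < max_padj
  out <- rl[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RankedGeneList", "data.frame")
  out
}

#' Robust rank aggregation rho score for one gene
#'
#' Given a gene's normalized ranks r_1..r_k across k of m ranked lists
#' (rank / list length, in (0,1]), sort them ascending and compute for each
#' order statistic j the binomial tail probability
#' `beta_j = P(Binomial(m, r_(j)) >= j)` — the chance that j or more of m
#' uniform ranks fall at or below r_(j). The rho score is `min_j beta_j`;
#' small rho means the gene sits improbably high across lists. Lists the
#' gene is missing from contribute no rank but m stays the total list count.
#'
#' @param normalized_ranks Numeric vector in (0, 1].
#' @param m Total number of lists aggregated.
#' @return rho, a single number in (0, 1].
#' @export
rra_rho <- function(normalized_ranks, m) {
  k <- length(normalized_ranks)
  if (k == 0) stopf("no ranks supplied")
  if (k > m) stopf("more ranks (%d) than lists (%d)", k, m)
  if (any(normalized_ranks <= 0 | normalized_ranks > 1))
    stopf("normalized ranks must lie in (0, 1]")
  r <- sort(normalized_ranks)
  beta <- stats::pbinom(seq_len(k) - 1L, size = m, prob = r,
                        lower.tail = FALSE)
  min(beta)
}

#' Per-gene RRA score p-value
#'
#' Bonferroni correction of rho over the m order statistics:
#' `min(rho * m, 1)`.
#'
#' @param rho rho score from [rra_rho()].
#' @param m Number of lists.
#' @return Score p-value in (0, 1].
#' @export
rra_score_p <- function(rho, m) pmin(rho * m, 1)

#' Aggregate ranked gene lists into a consensus signature by RRA
#'
#' Over the union of all list members: per list the gene appears in, its
#' normalized rank is position / list length; [rra_rho()] with m = number of
#' lists gives the rho score; the per-gene score p is `min(rho * m, 1)`
#' (Bonferroni over order statistics), then Benjamini-Hochberg across genes
#' yields the adjusted rank p. Genes with adjusted rank p below `max_rank_p`
#' (strict) form the signature.
#'
#' When the input lists are pre-filtered fragments of a larger ranking
#' (e.g. only the significantly upregulated genes of a differential
#' expression over the whole transcriptome), supply the size of the full
#' ranking as `universe_size` so positions are normalized against it —
#' the partial-list convention of the aggregation method. By default
#' positions are normalized by each list's own length.
#'
#' @param lists List of >= 2 `RankedGeneList`s sharing a gene namespace.
#' @param max_rank_p Threshold on the adjusted rank p (default 0.05).
#' @param across_gene_adjust `"BH"` (default) or `"none"` for the
#'   across-gene stage.
#' @param name Signature name.
#' @param direction Direction tag for the output signature.
#' @param universe_size Optional total size of the ranking each list was
#'   drawn from; positions are divided by it instead of the list length.
#' @return A `GeneSignature` with attribute `"table"` holding per-gene
#'   (gene_id, rho, score_p, rank_p_adj) for the full union.
#' @export
rra_aggregate <- function(lists, max_rank_p = 0.05,
                          across_gene_adjust = c("BH", "none"),
                          name = "rra_consensus", direction = "up",
                          universe_size = NULL) {
  across_gene_adjust <- match.arg(across_gene_adjust)
  if (length(lists) < 2) stopf("rra_aggregate needs >= 2 lists")
  m <- length(lists)
  universe <- unique(unlist(lapply(lists, function(l) l$gene_id)))
  if (length(universe) == 0) stopf("empty gene universe")
  if (!is.null(universe_size) &&
      universe_size < max(vapply(lists, nrow, integer(1))))
    stopf("universe_size smaller than a list")
  ranks <- lapply(lists, function(l) {
    stats::setNames(seq_len(nrow(l)) / (universe_size %||% nrow(l)),
                    l$gene_id)
  })
  rho <- vapply(universe, function(g) {
    r <- unlist(lapply(ranks, function(rk) rk[g]), use.names = FALSE)
    rra_rho(r[!is.na(r)], m)
  }, numeric(1))
  score_p <- rra_score_p(rho, m)
  rank_p_adj <- if (across_gene_adjust == "BH") stats::p.adjust(score_p, "BH")
                else score_p
  tab <- data.frame(gene_id = universe, rho = rho, score_p = score_p,
                    rank_p_adj = rank_p_adj, stringsAsFactors = FALSE)
  tab <- tab[order(tab$rho, tab$gene_id), ]
  rownames(tab) <- NULL
  keep <- tab$gene_id[tab$rank_p_adj < max_rank_p]
  if (length(keep) == 0)
    stopf("no gene passes adjusted rank p < %g", max_rank_p)
  sig <- gene_signature(name, keep, direction = direction)
  attr(sig, "table") <- tab
  sig
}

#' Majority-vote consensus of gene signatures
#'
#' Genes present in at least `min_support` of the input signatures.
#'
#' @param lists List of `GeneSignature`s.
#' @param min_support Minimum number of supporting lists (default 5).
#' @param name Output signature name.
#' @return A `GeneSignature`, or an empty-gene placeholder with a warning
#'   when `min_support` exceeds the number of lists.
#' @export
consensus_majority <- function(lists, min_support = 5, name = "consensus") {
  if (length(lists) < 1) stopf("need >= 1 signature")
  if (min_support > length(lists)) {
    warnf("min_support (%d) exceeds number of lists (%d); empty consensus",
          min_support, length(lists))
    out <- structure(list(name = name, genes = character(0), direction = "up"),
                     class = "GeneSignature")
    return(out)
  }
  counts <- table(unlist(lapply(lists, function(s) s$genes)))
  keep <- names(counts)[counts >= min_support]
  if (length(keep) == 0) {
    warnf("no gene reaches support %d; empty consensus", min_support)
    return(structure(list(name = name, genes = character(0), direction = "up"),
                     class = "GeneSignature"))
  }
  gene_signature(name, sort(keep), direction = lists[[1]]$direction)
}

#' Top-n signature from a ranked list
#'
#' @param rl `RankedGeneList`, sorted descending by log2fc.
#' @param n Number of genes (default 200); shorter lists return everything.
#' @param name Output signature name.
#' @return A `GeneSignature` (empty with a warning when n = 0).
#' @export
top_n_signature <- function(rl, n = 200, name = "top_n") {
  if (n == 0) {
    warnf("n = 0: empty signature")
    return(structure(list(name = name, genes = character(0), direction = "up"),
                     class = "GeneSignature"))
  }
  gene_signature(name, utils::head(rl$gene_id, n), direction = "up")
}

#' Map a signature through an ortholog table
#'
#' Replaces each member with its orthologous target gene(s); one-to-many
#' mappings contribute all targets, duplicates collapse, unmapped members
#' are dropped and counted in the `"unmapped"` attribute.
#'
#' @param sig `GeneSignature` in the source namespace.
#' @param ortho `data.frame` with columns `source`, `target`
#'   (see [read_ortholog_map()]).
#' @return A `GeneSignature` in the target namespace.
#' @export
map_orthologs <- function(sig, ortho) {
  hit <- ortho[ortho$source %in% sig$genes, , drop = FALSE]
  unmapped <- setdiff(sig$genes, hit$source)
  targets <- unique(hit$target)
  if (length(targets) == 0)
    stopf("no ortholog targets: %d/%d members unmapped",
          length(unmapped), length(sig$genes))
  out <- gene_signature(paste0(sig$name, "_ortholog"), sort(targets),
                        direction = sig$direction)
  attr(out, "unmapped") <- length(unmapped)
  attr(out, "unmapped_fraction") <- length(unmapped) / length(sig$genes)
  out
}
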