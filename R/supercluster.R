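#' Highly variable genes by standardized variance
#'
#' Dispersion statistic in the style of variance-stabilizing feature
#' selection: a loess trend of log10 variance on log10 mean over expressed
#' genes predicts each gene's expected standard deviation; values are
#' standardized by it, clipped at `sqrt(n_cells)`, and the variance of the
#' clipped standardized values ranks the genes. Deterministic.
#'
#' @param m `ExpressionMatrix`, lognorm layer, single cell line.
#' @param n Number of genes to return (default 2000); if `n` exceeds the
#'   gene count all genes are returned with a warning.
#' @param span Loess span for the mean-variance trend (default 0.3).
#' @return Character vector of gene ids, most variable first.
#' @export
variable_genes <- function(m, n = 2000, span = 0.3) {
  if (m$layer != "lognorm") stopf("variable_genes expects lognorm layer")
  if (length(unique(m$cell_meta$cell_line)) > 1)
    stopf("variable_genes expects a single cell line")
  v <- as.matrix(m$values)
  n_cells <- ncol(v)
  mu <- rowMeans(v)
  va <- rowSums((v - mu)^2) / (n_cells - 1)
  ok <- mu > 0 & va > 0
  std_var <- rep(0, nrow(v))
  if (sum(ok) > 10) {
    fit <- stats::loess(log10(va[ok]) ~ log10(mu[ok]), span = span,
                        degree = 2)
    sd_exp <- sqrt(10^stats::predict(fit))
    clip <- sqrt(n_cells)
    z <- (v[ok, , drop = FALSE] - mu[ok]) / sd_exp
    z <- pmin(pmax(z, -clip), clip)
    std_var[ok] <- rowSums((z - rowMeans(z))^2) / (n_cells - 1)
  } else {
    std_var <- va
  }
  if (n > nrow(v)) {
    warnf("n (%d) exceeds gene count (%d); returning all genes", n, nrow(v))
    n <- nrow(v)
  }
  ord <- order(-std_var, rownames(v))
  rownames(v)[ord][seq_len(n)]
}

#' Intersection of per-line variable-gene lists
#'
#' @param per_line_lists List (length >= 2) of gene-id vectors.
#' @return Character vector, the set intersection sorted lexicographically.
#' @export
shared_variable_genes <- function(per_line_lists) {
  if (length(per_line_lists) < 2) stopf("need >= 2 lists")
  shared <- Reduce(intersect, per_line_lists)
  if (length(shared) == 0) stopf("empty intersection of variable genes")
  sort(shared)
}

#' Differential mean-expression vector of a cluster
#'
#' For each gene in `genes`: mean expression in the cluster minus mean
#' expression across all other cells of the same cell line.
#'
#' @param m `ExpressionMatrix`, lognorm layer, single cell line.
#' @param cluster Cluster id.
#' @param genes Gene ids defining the vector (order preserved).
#' @return Named numeric vector of length `length(genes)`.
#' @export
differential_mean_vector <- function(m, cluster, genes) {
  if (length(unique(m$cell_meta$cell_line)) > 1)
    stopf("differential_mean_vector expects a single cell line")
  inC <- m$cell_meta$cluster == cluster
  if (!any(inC)) stopf("cluster '%s' is empty", cluster)
  if (all(inC)) stopf("cluster '%s' has no same-line complement", cluster)
  gi <- match(genes, rownames(m$values))
  if (anyNA(gi)) stopf("genes absent from matrix: %s",
                       paste(utils::head(genes[is.na(gi)], 5), collapse = ", "))
  v <- m$values[gi, , drop = FALSE]
  stats::setNames(
    as.numeric(Matrix::rowMeans(v[, inC, drop = FALSE]) -
                 Matrix::rowMeans(v[, !inC, drop = FALSE])),
    genes)
}

#' All-by-all Spearman correlation of cluster vectors
#'
#' @param vectors Named list of equal-length numeric vectors (length >= 3),
#'   one per cluster.
#' @return Symmetric Spearman correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(vectors) {
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1 || lens[1] < 3)
    stopf("vectors must share one length >= 3")
  const <- vapply(vectors, function(x) stats::var(x) == 0, logical(1))
  if (any(const))
    stopf("constant vector(s): %s — Spearman undefined",
          paste(names(vectors)[const], collapse = ", "))
  mat <- do.call(cbind, vectors)
  rho <- stats::cor(mat, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Group RACs across cell lines into superclusters
#'
#' Hierarchical clustering (average linkage on distance 1 - rho) of the
#' cluster correlation matrix, cut at height `cut`. A tree group becomes a
#' supercluster when it contains RACs from at least `min_lines` distinct
#' cell lines; only its RAC members are assigned (non-RAC clusters inform
#' the correlation structure but cannot join a supercluster). Supercluster
#' ids are SC1, SC2, ... ordered by the first member name, so the result
#' does not depend on input order.
#'
#' @param corr Correlation matrix from [correlation_matrix()]; row names
#'   are cluster ids.
#' @param rac_flags Named logical: is each cluster a RAC.
#' @param cell_lines Named character: cell line of each cluster.
#' @param min_lines Minimum number of distinct lines with a RAC in the
#'   group (default 2).
#' @param cut Tree cut height on 1 - rho (default 0.7).
#' @return A `SuperclusterGrouping`: list with `assignment` (data.frame of
#'   cluster_id, cell_line, is_rac, supercluster — NA when unassigned),
#'   `corr`, `tree` (the `hclust` object), `cut`, `min_lines`.
#' @export
group_superclusters <- function(corr, rac_flags, cell_lines,
                                min_lines = 2, cut = 0.7) {
  ids <- rownames(corr)
  ord <- order(ids)                       # input-order invariance
  corr <- corr[ord, ord, drop = FALSE]
  ids <- rownames(corr)
  rac_flags <- rac_flags[ids]
  cell_lines <- cell_lines[ids]
  tree <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  grp <- stats::cutree(tree, h = cut)
  assignment <- rep(NA_character_, length(ids))
  names(assignment) <- ids
  sc_members <- list()
  for (g in unique(grp)) {
    memb <- ids[grp == g]
    racs <- memb[rac_flags[memb]]
    if (length(unique(cell_lines[racs])) >= min_lines)
      sc_members[[length(sc_members) + 1]] <- racs
  }
  if (length(sc_members) == 0) {
    warnf("no group of RACs spans >= %d cell lines; empty assignment",
          min_lines)
  } else {
    sc_members <- sc_members[order(vapply(sc_members, min, character(1)))]
    for (i in seq_along(sc_members))
      assignment[sc_members[[i]]] <- paste0("SC", i)
  }
  structure(list(
    assignment = data.frame(cluster_id = ids, cell_line = unname(cell_lines),
                            is_rac = unname(rac_flags),
                            supercluster = unname(assignment),
                            stringsAsFactors = FALSE),
    corr = corr, tree = tree, cut = cut, min_lines = min_lines),
    class = "SuperclusterGrouping")
}

#' @export
print.SuperclusterGrouping <- function(x, ...) {
  sc <- stats::na.omit(unique(x$assignment$supercluster))
  cat(sprintf("SuperclusterGrouping: %d clusters, %d superclusters (cut %.2f, min_lines %d)\n",
              nrow(x$assignment), length(sc), x$cut, x$min_lines))
  invisible(x)
}

#' Consensus signature for a supercluster
#'
#' Each component RAC's differential-expression list is filtered by
#' direction (strict `log2fc > 0` for "up", `< 0` for "down";
#' `p_adj < 0.05`), re-sorted by |log2fc|, and the filtered lists are
#' aggregated with [rra_aggregate()] at adjusted rank p < `max_rank_p`.
#'
#' @param component_de List of >= 2 `RankedGeneList`s, one per component
#'   RAC (computed vs same-line non-RAC cells).
#' @param direction `"up"` (default) or `"down"`.
#' @param max_padj Per-list DE filter threshold (default 0.05).
#' @param max_rank_p RRA retention threshold (default 0.05).
#' @param name Signature name.
#' @param universe_size Size of the DE ranking the component lists were
#'   filtered from (default: the largest unfiltered list length); passed
#'   to [rra_aggregate()] so filtered-list positions are normalized
#'   against the full transcriptome.
#' @return A `GeneSignature`; empty (with a warning) when no gene survives.
#' @export
supercluster_signature <- function(component_de, direction = c("up", "down"),
                                   max_padj = 0.05, max_rank_p = 0.05,
                                   name = "supercluster_consensus",
                                   universe_size = NULL) {
  direction <- match.arg(direction)
  if (length(component_de) < 2) stopf("need >= 2 component lists")
  universe_size <- universe_size %||%
    max(vapply(component_de, nrow, integer(1)))
  filtered <- lapply(component_de, function(rl) {
    f <- if (direction == "up") filter_up(rl, 0, max_padj)
         else filter_down(rl, 0, max_padj)
    if (nrow(f) == 0) return(f)
    ranked_gene_list(f$gene_id, abs(f$log2fc), f$p, f$p_adj)
  })
  if (any(vapply(filtered, nrow, integer(1)) == 0)) {
    warnf("a component list is empty after filtering; empty signature")
    return(structure(list(name = name, genes = character(0),
                          direction = direction), class = "GeneSignature"))
  }
  out <- tryCatch(
    rra_aggregate(filtered, max_rank_p = max_rank_p, name = name,
                  direction = direction, universe_size = universe_size),
    error = function(e) {
      warnf("no gene passes aggregation; empty signature")
      structure(list(name = name, genes = character(0),
                     direction = direction), class = "GeneSignature")
    })
  out
}
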