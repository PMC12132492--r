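#' Filter cells by detected-feature count
#'
#' Retains cells whose number of detected genes (strictly positive counts)
#' lies in `[min_features, max_features]`, the standard single-cell QC gate.
#' A cell's feature count depends only on its own column, so the filter is
#' identical whether applied per cell line or globally.
#'
#' @param m `ExpressionMatrix`, counts layer.
#' @param min_features,max_features Inclusive bounds on detected genes per
#'   cell (defaults 200 and 2500).
#' @return Filtered `ExpressionMatrix`; the gene axis is unchanged.
#' @export
filter_cells <- function(m, min_features = 200, max_features = 2500) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stopf("filter_cells expects the counts layer")
  if (min_features < 0 || min_features > max_features)
    stopf("need 0 <= min_features <= max_features")
  nfeat <- Matrix::colSums(m$values > 0)
  keep <- nfeat >= min_features & nfeat <= max_features
  if (!any(keep)) stopf("no cells pass QC (bounds %d..%d)",
                        min_features, max_features)
  subset_matrix(m, cells = which(keep))
}

#' Filter genes by the number of cells detecting them
#'
#' Retains genes detected (count > 0) in at least `min_cells` cells. With
#' `per_line = TRUE` (default) the threshold is applied within each cell
#' line and a gene is kept when it passes in at least one line, keeping a
#' multi-line matrix rectangular while honoring within-line filtering.
#'
#' @param m `ExpressionMatrix`, counts layer.
#' @param min_cells Minimum number of detecting cells (default 100).
#' @param per_line Apply the threshold within each cell line.
#' @return Filtered `ExpressionMatrix`; the cell axis is unchanged.
#' @export
filter_genes <- function(m, min_cells = 100, per_line = TRUE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stopf("filter_genes expects the counts layer")
  det <- m$values > 0
  if (per_line && length(unique(m$cell_meta$cell_line)) > 1) {
    lines <- unique(m$cell_meta$cell_line)
    keep <- rep(FALSE, nrow(m$values))
    for (ln in lines) {
      idx <- m$cell_meta$cell_line == ln
      keep <- keep | Matrix::rowSums(det[, idx, drop = FALSE]) >= min_cells
    }
  } else {
    keep <- Matrix::rowSums(det) >= min_cells
  }
  if (!any(keep))
    stopf("no genes detected in >= %d cells; all genes removed", min_cells)
  subset_matrix(m, genes = which(keep))
}

#' Log-normalize counts
#'
#' Per cell: `log(1 + count / total * scale)` in base `base` (natural log by
#' default), the library-size normalization standard in droplet single-cell
#' workflows. Columns are independent, so a cell's normalized profile is
#' invariant to scaling all its counts.
#'
#' @param m `ExpressionMatrix`, counts layer; every cell needs total > 0.
#' @param scale Scale factor (default 10000).
#' @param base Log base (default `exp(1)`); recorded in the output `norm`
#'   metadata.
#' @return `ExpressionMatrix` with `layer = "lognorm"`.
#' @export
lognormalize <- function(m, scale = 10000, base = exp(1)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stopf("lognormalize expects the counts layer")
  tot <- Matrix::colSums(m$values)
  if (any(tot == 0))
    stopf("cell(s) with zero total count: %s",
          paste(utils::head(colnames(m$values)[tot == 0], 5), collapse = ", "))
  v <- m$values
  # operate on the sparse slots: zeros map to log1p(0) = 0
  cell_of <- rep(seq_len(ncol(v)), diff(v@p))
  v@x <- log1p(v@x / tot[cell_of] * scale) / log(base)
  expression_matrix(v, m$cell_meta, layer = "lognorm",
                    norm = list(scale = scale, log_base = base))
}
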