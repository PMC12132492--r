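#' Gene-by-cell expression container
#'
#' A light container for a gene x cell (or gene x sample) expression matrix
#' together with per-cell metadata and a layer tag recording whether the
#' values are raw counts or log-normalized units.
#'
#' @param values Numeric matrix or `Matrix::dgCMatrix`, genes in rows, cells
#'   in columns; non-negative. Row and column names are the gene and cell
#'   identifiers and must be unique.
#' @param cell_meta `data.frame` with one row per cell. Recognized columns:
#'   `cell_id`, `cell_line`, `cluster`, `treated` (logical), `drug`,
#'   `drug_class`. `cell_line` and `cluster` are required; missing optional
#'   columns are filled with `NA`.
#' @param layer `"counts"` or `"lognorm"`.
#' @param norm For `lognorm` layers, a list recording `scale` and `log_base`.
#'
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, cell_meta, layer = c("counts", "lognorm"),
                              norm = NULL) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("values must carry gene row names and cell column names")
  if (!methods::is(values, "sparseMatrix")) {
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  }
  values <- methods::as(values, "CsparseMatrix")
  m <- structure(
    list(values = values, cell_meta = as_cell_meta(cell_meta, colnames(values)),
         layer = layer, norm = norm),
    class = "ExpressionMatrix"
  )
  validate_expression_matrix(m)
  m
}

as_cell_meta <- function(cell_meta, cell_ids) {
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(cell_meta)) cell_meta$cell_id <- cell_ids
  for (col in c("cell_line", "cluster")) {
    if (!col %in% names(cell_meta))
      stopf("cell_meta lacks required column '%s'", col)
  }
  if (!"treated" %in% names(cell_meta)) cell_meta$treated <- NA
  if (!"drug" %in% names(cell_meta)) cell_meta$drug <- NA_character_
  if (!"drug_class" %in% names(cell_meta)) cell_meta$drug_class <- NA_character_
  cell_meta$treated <- as.logical(cell_meta$treated)
  rownames(cell_meta) <- NULL
  cols <- c("cell_id", "cell_line", "cluster", "treated", "drug", "drug_class")
  cell_meta[, c(cols, setdiff(names(cell_meta), cols)), drop = FALSE]
}

validate_expression_matrix <- function(m) {
  v <- m$values
  if (anyDuplicated(rownames(v))) stopf("gene ids are not unique")
  if (anyDuplicated(colnames(v))) stopf("cell ids are not unique")
  if (nrow(m$cell_meta) != ncol(v))
    stopf("cell_meta rows (%d) do not match cell count (%d)",
          nrow(m$cell_meta), ncol(v))
  if (!identical(m$cell_meta$cell_id, colnames(v)))
    stopf("cell_meta$cell_id does not match matrix column names")
  if (any(v@x < 0)) stopf("expression values must be non-negative")
  if (m$layer == "lognorm" && any(!is.finite(v@x)))
    stopf("lognorm values must be finite")
  if (anyNA(m$cell_meta$cluster) || anyNA(m$cell_meta$cell_line))
    stopf("every cell needs a cluster and a cell_line label")
  invisible(m)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  cat(sprintf("  cell lines: %s\n",
              paste(unique(x$cell_meta$cell_line), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Cell identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector.
#' @export
cell_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix
#'
#' @param m An `ExpressionMatrix`.
#' @param genes Gene ids or index vector (default all).
#' @param cells Cell ids or index vector (default all).
#' @return An `ExpressionMatrix`.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% seq_len(nrow(m$values))
  cells <- cells %||% seq_len(ncol(m$values))
  v <- m$values[genes, cells, drop = FALSE]
  idx <- match(colnames(v), m$cell_meta$cell_id)
  expression_matrix(v, m$cell_meta[idx, , drop = FALSE],
                    layer = m$layer, norm = m$norm)
}

# ---------------------------------------------------------------------------
# MatrixMarket + TSV sidecar i/o

#' Write an ExpressionMatrix as MTX with TSV sidecars
#'
#' Files written under `dir`: `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#' `cell_meta.tsv` and `layer.txt` (layer tag plus normalization record).
#'
#' @param m An `ExpressionMatrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_expression_mtx <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$values, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m$values), file.path(dir, "genes.tsv"))
  writeLines(colnames(m$values), file.path(dir, "barcodes.tsv"))
  utils::write.table(m$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(layer = m$layer, norm = m$norm)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(dir, "layer.txt"))
  invisible(dir)
}

#' Read an ExpressionMatrix written by [write_expression_mtx()]
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`,
#'   `cell_meta.tsv` and optionally `layer.txt`.
#' @return An `ExpressionMatrix`.
#' @export
read_expression_mtx <- function(dir) {
  v <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(v) <- readLines(file.path(dir, "genes.tsv"))
  colnames(v) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(cell_id = "character",
                                           cluster = "character"))
  layer <- "counts"; norm <- NULL
  lf <- file.path(dir, "layer.txt")
  if (file.exists(lf)) {
    rec <- jsonlite::fromJSON(readLines(lf, warn = FALSE))
    layer <- rec$layer
    norm <- rec$norm
  }
  expression_matrix(v, meta, layer = layer, norm = norm)
}

# ---------------------------------------------------------------------------
# GMT gene-set collections

#' Read gene sets from a GMT file
#'
#' @param path GMT file (name, description, tab-separated members).
#' @param direction Direction tag applied to all sets.
#' @return Named list of [gene_signature()] objects.
#' @export
read_gene_sets <- function(path, direction = "unsigned") {
  sets <- fgsea::gmtPathways(path)
  out <- lapply(names(sets), function(nm)
    gene_signature(nm, sets[[nm]], direction = direction))
  names(out) <- names(sets)
  out
}

#' Write gene signatures to a GMT file
#'
#' @param sigs A `GeneSignature` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sigs, path) {
  if (inherits(sigs, "GeneSignature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s)
    paste(c(s$name, s$direction, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ranked-list and table i/o

#' Write a ranked gene list as TSV
#' @param rl A `RankedGeneList` (see [ranked_gene_list()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(rl, path) {
  utils::write.table(as.data.frame(unclass(rl))[, c("gene_id", "log2fc", "p", "p_adj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked gene list from TSV
#' @param path TSV with columns gene_id, log2fc, p, p_adj.
#' @return A `RankedGeneList`.
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character"))
  ranked_gene_list(df$gene_id, df$log2fc, df$p, df$p_adj)
}

#' Read a two-column ortholog mapping table
#' @param path TSV with a header and two columns: source gene, target gene.
#' @return `data.frame` with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("ortholog map needs two columns")
  names(df)[1:2] <- c("source", "target")
  df[, 1:2]
}

#' Read a survival cohort table
#' @param path TSV with columns sample_id, time, event and optional
#'   age, sex, purity.
#' @return `data.frame` of survival records.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  if (any(df$time <= 0)) stopf("survival times must be positive")
  df$event <- as.logical(df$event)
  df
}

#' Write a survival cohort table
#' @param records Survival `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
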