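#' Cluster activity odds ratio
#'
#' `(a_in / i_in) / (a_out / i_out)`: the odds of being active inside the
#' cluster over the odds outside it. Boundary conventions: 0 when no active
#' cell inside; `+Inf` when the inside has no inactive cell (with active
#' present) or the outside has no active cell (with inactive present); both
#' ratios degenerate is an error.
#'
#' @param a_in,i_in Active / inactive cells inside the cluster.
#' @param a_out,i_out Active / inactive cells outside the cluster.
#' @return A single non-negative number, possibly `Inf`.
#' @export
cluster_odds_ratio <- function(a_in, i_in, a_out, i_out) {
  if (any(c(a_in, i_in, a_out, i_out) < 0)) stopf("counts must be >= 0")
  if (a_in + i_in == 0 || a_out + i_out == 0)
    stopf("empty cluster or empty complement")
  num_deg <- (a_in == 0 && i_in == 0) || (a_in > 0 && i_in == 0)
  den_deg <- (a_out == 0 && i_out == 0) || (a_out > 0 && i_out == 0)
  if (a_in == 0 && a_out == 0)
    stopf("odds ratio undefined: no active cells anywhere")
  if (i_in == 0 && i_out == 0)
    stopf("odds ratio undefined: no inactive cells anywhere")
  if (a_in == 0) return(0)
  if (i_in == 0) return(Inf)               # all inside active
  if (a_out == 0) return(Inf)              # outside has no active
  if (i_out == 0) return(0)                # outside all active, inside not
  (a_in / i_in) / (a_out / i_out)
}

#' Fisher exact test p-value for a 2x2 table
#'
#' Exact hypergeometric p; the two-sided p sums the probabilities of all
#' tables no more probable than the observed one (the R convention).
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2), alternative = alt)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param pvals Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values outside [0,1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Call resistance-activated clusters (RACs)
#'
#' Per cell line, each cluster is tested against all other clusters of the
#' same line with a 2x2 table of activity calls: odds ratio by
#' [cluster_odds_ratio()], p by two-sided [fisher_exact()], BH adjustment
#' across that line's clusters. A cluster is a RAC when `odds_ratio >
#' or_min` and `p_adj < padj_max` (both strict). When the metadata carries
#' informative `treated` flags, each RAC is additionally classified
#' `pre_existing` (calling RACs on the untreated cells alone, with the same
#' threshold, also flags it) or `emergent`.
#'
#' @param activity `ActivityResult` from [score_activity()] (or any list
#'   with a named logical `active`).
#' @param cell_meta Per-cell metadata covering exactly the scored cells
#'   (columns `cell_id`, `cell_line`, `cluster`, optionally `treated`).
#' @param or_min Odds-ratio threshold (default 1, strict).
#' @param padj_max Adjusted-p threshold (default 0.05, strict).
#' @param classify_status Classify RACs as pre-existing vs emergent using
#'   untreated cells (default TRUE when treated flags are informative).
#' @return A `data.frame` (class `RACTable`) with one row per cluster:
#'   cell_line, cluster_id, n_active, n_inactive, odds_ratio, p, p_adj,
#'   is_rac, status.
#' @export
call_racs <- function(activity, cell_meta, or_min = 1, padj_max = 0.05,
                      classify_status = TRUE) {
  active <- activity$active
  meta <- cell_meta[match(names(active), cell_meta$cell_id), , drop = FALSE]
  if (anyNA(meta$cell_id))
    stopf("activity calls and metadata cover different cells")
  tab <- rac_table_core(active, meta, or_min, padj_max)
  tab$status <- "none"
  has_untreated <- "treated" %in% names(meta) && !anyNA(meta$treated) &&
    any(!meta$treated) && any(meta$treated)
  if (classify_status && has_untreated && any(tab$is_rac)) {
    un <- !meta$treated
    pre <- tryCatch(
      rac_table_core(active[un], meta[un, , drop = FALSE], or_min, padj_max),
      error = function(e) NULL)
    for (i in which(tab$is_rac)) {
      hit <- !is.null(pre) &&
        any(pre$is_rac & pre$cell_line == tab$cell_line[i] &
              pre$cluster_id == tab$cluster_id[i])
      tab$status[i] <- if (hit) "pre_existing" else "emergent"
    }
  } else if (any(tab$is_rac)) {
    tab$status[tab$is_rac] <- NA_character_
  }
  class(tab) <- c("RACTable", "data.frame")
  tab
}

rac_table_core <- function(active, meta, or_min, padj_max) {
  out <- list()
  for (ln in unique(meta$cell_line)) {
    idx <- meta$cell_line == ln
    cl <- meta$cluster[idx]
    act <- active[idx]
    clusters <- sort(unique(cl))
    if (length(clusters) < 2)
      stopf("cell line '%s' has a single cluster: no background", ln)
    rows <- lapply(clusters, function(cc) {
      inC <- cl == cc
      a_in <- sum(act & inC); i_in <- sum(!act & inC)
      a_out <- sum(act & !inC); i_out <- sum(!act & !inC)
      or <- tryCatch(cluster_odds_ratio(a_in, i_in, a_out, i_out),
                     error = function(e) NA_real_)
      p <- fisher_exact(a_in, i_in, a_out, i_out)
      data.frame(cell_line = ln, cluster_id = cc,
                 n_active = a_in, n_inactive = i_in,
                 odds_ratio = or, p = p, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$p_adj <- bh_adjust(df$p)
    df$is_rac <- !is.na(df$odds_ratio) & df$odds_ratio > or_min &
      df$p_adj < padj_max
    out[[ln]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a RAC table as TSV
#' @param tab `RACTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rac_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drug-class enrichment in a cluster group
#'
#' Among treated cells, tests whether cells treated with each drug class
#' are overrepresented in a set of member clusters: 2x2 of (in member
#' clusters vs not) by (treated with the class vs other classes), odds
#' ratio by [cluster_odds_ratio()] arithmetic, two-sided Fisher p, BH
#' across classes. Counts are accumulated within each cell line containing
#' member clusters and pooled.
#'
#' @param cell_meta Per-cell metadata with `cluster`, `cell_line`,
#'   `treated`, `drug_class`.
#' @param member_clusters Cluster ids forming the group.
#' @param drug_class Optional single class; default tests every class
#'   present among treated cells.
#' @return `data.frame`: drug_class, n_in, n_out, odds_ratio, p, p_adj.
#' @export
drug_class_enrichment <- function(cell_meta, member_clusters, drug_class = NULL) {
  treated <- cell_meta[which(cell_meta$treated %in% TRUE &
                               !is.na(cell_meta$drug_class)), , drop = FALSE]
  if (nrow(treated) == 0) stopf("no treated cells with a drug class")
  lines_in <- unique(treated$cell_line[treated$cluster %in% member_clusters])
  treated <- treated[treated$cell_line %in% lines_in, , drop = FALSE]
  classes <- drug_class %||% sort(unique(treated$drug_class))
  in_member <- treated$cluster %in% member_clusters
  rows <- lapply(classes, function(dc) {
    if (!dc %in% treated$drug_class) {
      warnf("drug class '%s' absent; row skipped", dc)
      return(NULL)
    }
    is_dc <- treated$drug_class == dc
    a <- sum(is_dc & in_member);  b <- sum(!is_dc & in_member)
    c_ <- sum(is_dc & !in_member); d <- sum(!is_dc & !in_member)
    or <- tryCatch(cluster_odds_ratio(a, b, c_, d),
                   error = function(e) NA_real_)
    data.frame(drug_class = dc, n_in = a, n_out = c_,
               odds_ratio = or, p = fisher_exact(a, b, c_, d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stopf("no testable drug class")
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}
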