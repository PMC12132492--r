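#' Per-cell expression rankings for recovery-curve scoring
#'
#' For every cell, ranks all genes by descending expression (rank 1 = most
#' expressed) with ties broken by a seeded random permutation. Computing
#' the rankings once and reusing them across gene sets is what makes the
#' 100-repeat control-threshold procedure cheap: only the gene set changes
#' between repeats, never the ranking.
#'
#' @param m `ExpressionMatrix`.
#' @param seed Integer seed for the tie-breaking permutation.
#' @return Integer matrix (genes x cells) of ranks, with dimnames.
#' @export
aucell_rankings <- function(m, seed = 1) {
  v <- as.matrix(m$values)
  with_seed(seed, {
    apply(v, 2, function(col) rank(-col, ties.method = "random"))
  })
}

#' Area-under-recovery-curve gene-set activity score
#'
#' Per cell, genes are ranked by descending expression; the recovery step
#' curve y(x) counts signature genes among the top x ranks for
#' x = 1..R, R = `ceiling(max_rank_fraction * n_genes)`. The score is the
#' step-curve area divided by the area of the ideal curve in which all
#' `min(|sig|, R)` signature genes occupy the top ranks, so it lies in
#' `[0, 1]` and equals 1 exactly when the signature fills the top of the
#' ranking. Being rank-based, the score is invariant to any strictly
#' monotone transform of a cell's expression values.
#'
#' @param m `ExpressionMatrix` (ignored when `rankings` is supplied).
#' @param sig `GeneSignature`; a warning is issued when < 80% of its genes
#'   are present in the matrix, an error when none are.
#' @param max_rank_fraction Fraction of top-ranked genes forming the
#'   recovery window (default 0.05).
#' @param seed Seed for rank tie-breaking (ignored when `rankings` given).
#' @param rankings Optional precomputed [aucell_rankings()] matrix.
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
aucell_score <- function(m, sig, max_rank_fraction = 0.05, seed = 1,
                         rankings = NULL) {
  if (max_rank_fraction <= 0 || max_rank_fraction > 1)
    stopf("max_rank_fraction must lie in (0, 1]")
  if (is.null(rankings)) rankings <- aucell_rankings(m, seed)
  genes <- rownames(rankings)
  present <- intersect(sig$genes, genes)
  if (length(present) == 0)
    stopf("no gene of signature '%s' present in the matrix", sig$name)
  if (length(present) < 0.8 * length(sig$genes))
    warnf("only %d/%d genes of '%s' present in the matrix",
          length(present), length(sig$genes), sig$name)
  n_genes <- nrow(rankings)
  R <- ceiling(max_rank_fraction * n_genes)
  rk <- rankings[match(present, genes), , drop = FALSE]
  area <- Matrix::colSums(pmax(R + 1 - rk, 0))
  s_eff <- min(length(present), R)
  ideal <- sum(R + 1 - seq_len(s_eff))
  stats::setNames(as.numeric(area / ideal), colnames(rankings))
}

# equal-frequency expression bins over expressed genes (mean lognorm > 0)
expression_bins <- function(m, n_bins = 10) {
  means <- Matrix::rowMeans(m$values)
  expressed <- which(means > 0)
  if (length(expressed) < n_bins)
    stopf("fewer expressed genes (%d) than bins (%d)",
          length(expressed), n_bins)
  r <- rank(means[expressed], ties.method = "first")
  bin <- ceiling(r / length(expressed) * n_bins)
  stats::setNames(bin, rownames(m$values)[expressed])
}

# draw a bin-matched control set: for each signature gene, `per_gene`
# control genes from its expression bin, excluding signature members;
# exhausted bins fall back to the nearest bin with candidates.
draw_bin_controls <- function(bins, sig_genes, per_gene = 1) {
  sig_present <- intersect(sig_genes, names(bins))
  sig_bins <- bins[sig_present]
  candidates <- split(setdiff(names(bins), sig_genes), bins[setdiff(names(bins), sig_genes)])
  need <- table(sig_bins) * per_gene
  out <- character(0)
  warned <- FALSE
  for (b in names(need)) {
    n_need <- as.integer(need[[b]])
    pool <- candidates[[b]] %||% character(0)
    if (length(pool) < n_need) {
      # top up from nearest bins
      if (!warned) { warnf("expression bin %s short of control genes; using nearest bins", b); warned <- TRUE }
      all_bins <- as.integer(names(candidates))
      ord <- all_bins[order(abs(all_bins - as.integer(b)))]
      for (nb in ord) {
        if (length(pool) >= n_need) break
        extra <- setdiff(candidates[[as.character(nb)]], pool)
        pool <- c(pool, extra)
      }
    }
    take <- if (length(pool) >= n_need) sample(pool, n_need)
            else sample(pool, n_need, replace = TRUE)
    out <- c(out, take)
  }
  out
}

#' Activity threshold from expression-matched control gene sets
#'
#' Null model for calling a cell "active": expressed genes are placed into
#' `n_bins` equal-frequency bins by mean normalized expression; one repeat
#' draws, for each signature gene, a random gene from the same bin (a
#' control set of the signature's size), scores all cells with
#' [aucell_score()] on the control set, and stores the `pct`-th percentile
#' of those scores as a putative threshold. The final threshold is the
#' maximum putative threshold over `n_repeats` repeats, so it can only grow
#' with more repeats. A cell whose signature score exceeds the threshold is
#' considered active.
#'
#' @param m `ExpressionMatrix`, lognorm layer.
#' @param sig `GeneSignature`.
#' @param n_bins Number of expression bins (default 10).
#' @param pct Percentile of control scores per repeat (default 95).
#' @param n_repeats Number of control draws (default 100).
#' @param max_rank_fraction Passed to [aucell_score()].
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param rankings Optional precomputed [aucell_rankings()] matrix.
#' @return A single threshold in `[0, 1]`, with attribute
#'   `"putative"` holding the per-repeat thresholds.
#' @export
activity_threshold <- function(m, sig, n_bins = 10, pct = 95, n_repeats = 100,
                               max_rank_fraction = 0.05, seed = 1,
                               rankings = NULL) {
  if (m$layer != "lognorm") stopf("activity_threshold expects lognorm layer")
  if (is.null(rankings)) rankings <- aucell_rankings(m, derive_seed(seed, "rank"))
  bins <- expression_bins(m, n_bins)
  putative <- with_seed(derive_seed(seed, "ctrl"), {
    vapply(seq_len(n_repeats), function(i) {
      ctrl <- draw_bin_controls(bins, sig$genes, per_gene = 1)
      cs <- aucell_score(m, gene_signature("ctrl", ctrl),
                         max_rank_fraction = max_rank_fraction,
                         rankings = rankings)
      stats::quantile(cs, pct / 100, names = FALSE)
    }, numeric(1))
  })
  out <- max(putative)
  attr(out, "putative") <- putative
  out
}

#' Score cells and call signature activity
#'
#' Convenience wrapper combining [aucell_score()] and
#' [activity_threshold()] into an activity result: per-cell scores, the
#' control-set threshold, and boolean calls `score > threshold`.
#'
#' @inheritParams activity_threshold
#' @return An `ActivityResult`: list with `scores`, `threshold`, `active`,
#'   `signature_name`, `max_rank_fraction`, `seed`.
#' @export
score_activity <- function(m, sig, max_rank_fraction = 0.05, n_bins = 10,
                           pct = 95, n_repeats = 100, seed = 1) {
  rankings <- aucell_rankings(m, derive_seed(seed, "rank"))
  scores <- aucell_score(m, sig, max_rank_fraction, rankings = rankings)
  thr <- activity_threshold(m, sig, n_bins = n_bins, pct = pct,
                            n_repeats = n_repeats,
                            max_rank_fraction = max_rank_fraction,
                            seed = seed, rankings = rankings)
  structure(list(scores = scores, threshold = as.numeric(thr),
                 putative_thresholds = attr(thr, "putative"),
                 active = scores > as.numeric(thr),
                 signature_name = sig$name,
                 max_rank_fraction = max_rank_fraction, seed = seed),
            class = "ActivityResult")
}

#' @export
print.ActivityResult <- function(x, ...) {
  cat(sprintf("ActivityResult '%s': %d cells, threshold %.4f, %d active (%.1f%%)\n",
              x$signature_name, length(x$scores), x$threshold,
              sum(x$active), 100 * mean(x$active)))
  invisible(x)
}

#' Write activity scores as TSV
#' @param activity An `ActivityResult`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity <- function(activity, path) {
  df <- data.frame(cell_id = names(activity$scores),
                   signature = activity$signature_name,
                   score = as.numeric(activity$scores),
                   active = activity$active, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin-matched module score
#'
#' Per cell: mean expression of signature genes minus mean expression of a
#' bin-matched control pool (`ctrl_per_gene` random same-bin genes per
#' signature gene), the control construction shared with
#' [activity_threshold()].
#'
#' @param m `ExpressionMatrix`, lognorm layer.
#' @param sig `GeneSignature`.
#' @param n_bins Expression bins (default 10).
#' @param ctrl_per_gene Control genes drawn per signature gene (default 100).
#' @param seed Integer seed.
#' @return Named per-cell numeric vector.
#' @export
module_score <- function(m, sig, n_bins = 10, ctrl_per_gene = 100, seed = 1) {
  if (m$layer != "lognorm") stopf("module_score expects lognorm layer")
  present <- intersect(sig$genes, rownames(m$values))
  if (length(present) == 0) stopf("no signature gene present")
  bins <- expression_bins(m, n_bins)
  ctrl <- with_seed(derive_seed(seed, "module"),
                    draw_bin_controls(bins, sig$genes, per_gene = ctrl_per_gene))
  sig_mean <- Matrix::colMeans(m$values[match(present, rownames(m$values)), , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(m$values[match(ctrl, rownames(m$values)), , drop = FALSE])
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(m$values))
}

#' Assign cells to cell-cycle phases
#'
#' Scores each cell with [module_score()] for every phase signature and
#' labels it with the highest-scoring phase. Ties are broken by a fixed
#' priority order (first match in `priority` wins), recorded in the
#' `"priority"` attribute, so assignment is deterministic.
#'
#' @param m `ExpressionMatrix`, lognorm layer.
#' @param phase_sigs Named list of `GeneSignature`s; must include at least
#'   G0, G1, S and G2M.
#' @param seed Integer seed for control draws.
#' @param priority Tie-break order (default `c("G0","G1","S","G2M")`).
#' @param n_bins,ctrl_per_gene Passed to [module_score()].
#' @return Named character vector of per-cell phase labels, with the score
#'   matrix in attribute `"scores"`.
#' @export
assign_cell_cycle <- function(m, phase_sigs, seed = 1,
                              priority = c("G0", "G1", "S", "G2M"),
                              n_bins = 10, ctrl_per_gene = 100) {
  required <- c("G0", "G1", "S", "G2M")
  missing_ph <- setdiff(required, names(phase_sigs))
  if (length(missing_ph) > 0)
    stopf("missing phase signature(s): %s", paste(missing_ph, collapse = ", "))
  phases <- c(priority, setdiff(names(phase_sigs), priority))
  scores <- vapply(phases, function(ph)
    module_score(m, phase_sigs[[ph]], n_bins = n_bins,
                 ctrl_per_gene = ctrl_per_gene,
                 seed = derive_seed(seed, ph)),
    numeric(ncol(m$values)))
  # which.max returns the first maximum: priority order wins ties
  labels <- phases[apply(scores, 1, which.max)]
  out <- stats::setNames(labels, colnames(m$values))
  attr(out, "scores") <- scores
  attr(out, "priority") <- priority
  out
}

#' Single-sample GSEA score
#'
#' Ranks the sample's genes by descending value and walks the ranking,
#' accumulating rank-weight^alpha (normalized over in-set genes) for set
#' members and 1/(N - |set|) for non-members; the score is the sum over
#' positions of the difference of the two cumulative distributions, so it
#' is larger the more the set concentrates at the top of the ranking.
#'
#' @param sample_values Named numeric vector, one value per gene.
#' @param sig `GeneSignature`; must be a proper non-empty subset of the
#'   genes after intersection.
#' @param alpha Rank-weight exponent (default 0.25); `alpha = 0` gives the
#'   unweighted walk.
#' @return A single numeric score.
#' @export
ssgsea <- function(sample_values, sig, alpha = 0.25) {
  N <- length(sample_values)
  genes <- names(sample_values)
  if (is.null(genes)) stopf("sample_values must be named by gene")
  in_set <- genes %in% sig$genes
  s <- sum(in_set)
  if (s == 0) stopf("signature '%s' shares no gene with the sample", sig$name)
  if (s == N) stopf("signature equals the gene universe")
  rnk <- rank(sample_values, ties.method = "average")      # N = highest value
  ord <- order(-sample_values, genes)                      # deterministic ties
  in_ord <- in_set[ord]
  w <- rnk[ord]^alpha
  step_in <- ifelse(in_ord, w, 0)
  cdf_in <- cumsum(step_in) / sum(step_in)
  cdf_out <- cumsum(!in_ord) / (N - s)
  sum(cdf_in - cdf_out)
}

#' Preranked GSEA with gene-permutation null
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment: walking the
#' ranked list, set members add `|log2fc| / sum(|log2fc| over members)` and
#' non-members subtract `1/(N - |set|)`; ES is the extreme deviation. The
#' null permutes gene labels (random set positions); NES is ES divided by
#' the mean `|ES_perm|` of the same sign, and p is the same-sign
#' permutation tail fraction with a +1 pseudo-count.
#'
#' @param ranked `RankedGeneList` covering the scoring universe.
#' @param sig `GeneSignature`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `es`, `nes`, `p`.
#' @export
gsea <- function(ranked, sig, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  genes <- ranked$gene_id
  N <- length(genes)
  w <- abs(ranked$log2fc)
  pos <- which(genes %in% sig$genes)
  if (length(pos) == 0) stopf("signature shares no gene with the ranked list")
  if (length(pos) == N) stopf("signature equals the ranked universe")
  s <- length(pos)
  es_at <- function(positions) {
    p_sorted <- sort(positions)
    wh <- w[p_sorted]
    NR <- sum(wh)
    hit_cdf <- if (NR > 0) cumsum(wh) / NR else seq_along(p_sorted) / s
    miss_before <- (p_sorted - seq_along(p_sorted)) / (N - s)
    after <- hit_cdf - miss_before
    before <- c(0, hit_cdf[-s]) - (p_sorted - seq_along(p_sorted)) / (N - s)
    cand <- c(after, before)
    cand[which.max(abs(cand))]
  }
  es <- es_at(pos)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) es_at(sample.int(N, s)), numeric(1))
  })
  same <- perm[sign(perm) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, p = p)
}

#' Cohen's d standardized mean difference
#'
#' `(mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' weighted by n - 1.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return A single number.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stopf("each group needs >= 2 values")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(0)
    stopf("pooled standard deviation is zero")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration when the combined sample size is
#' <= 20 and tie-free, normal approximation with tie correction otherwise
#' (via `stats::wilcox.test`).
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (x vs y).
#' @return List with `statistic` (Mann-Whitney U of x) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  n <- length(x) + length(y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt,
                       exact = (n <= 20 && !has_ties))
  )
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
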