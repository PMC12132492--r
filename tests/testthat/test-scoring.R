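# Recovery-curve scoring, the control-set threshold null, module scores,
# ssGSEA, permutation GSEA, and the two-group statistics

test_that("recovery-curve score matches the worked step-curve cases", {
  m <- ladder_matrix(100)                      # ranking fully determined
  # all 5 signature genes in the top 5 ranks: ideal curve, score 1
  expect_equal(aucell_score(m, gene_signature("s", sprintf("g%03d", 1:5)),
                            max_rank_fraction = 0.05), c(c1 = 1))
  # no signature gene inside the window: score 0
  expect_equal(aucell_score(m, gene_signature("s", c("g099", "g100")),
                            max_rank_fraction = 0.05), c(c1 = 0))
  # hits at ranks {1, 3}, R = 5: area 8 over ideal area 9
  expect_equal(aucell_score(m, gene_signature("s", c("g001", "g003")),
                            max_rank_fraction = 0.05), c(c1 = 8 / 9))
})

test_that("recovery-curve score equals a brute-force step-curve oracle", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(10:50, 1)
    v <- matrix(rpois(n * 3, 4), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), c("c1", "c2", "c3")))
    m <- expression_matrix(v, data.frame(cell_id = colnames(v),
                                         cell_line = "L", cluster = "A"),
                           layer = "lognorm")
    sig <- gene_signature("s", sample(rownames(v), sample(2:5, 1)))
    frac <- runif(1, 0.1, 1)
    rk <- aucell_rankings(m, seed = i)
    got <- aucell_score(m, sig, frac, rankings = rk)
    R <- ceiling(frac * n)
    for (j in 1:3) {
      hits <- which(rownames(v)[order(rk[, j])] %in% sig$genes)
      y <- vapply(1:R, function(x) sum(hits <= x), numeric(1))
      s_eff <- min(length(sig$genes), R)
      ideal <- vapply(1:R, function(x) min(x, s_eff), numeric(1))
      expect_equal(unname(got[j]), sum(y) / sum(ideal))
    }
  }
})

test_that("recovery-curve score is invariant to monotone transforms", {
  m <- tiny_matrix()
  sig <- gene_signature("s", c("g01", "g05", "g08"))
  base <- aucell_score(m, sig, 0.5, seed = 3)
  v2 <- m$values
  v2@x <- exp(v2@x) - 0.5                       # strictly monotone on values
  m2 <- expression_matrix(v2, m$cell_meta, layer = "lognorm")
  expect_equal(aucell_score(m2, sig, 0.5, seed = 3), base)
})

test_that("threshold is the max over repeats and grows with repeats", {
  m <- small_lognorm()
  ml <- subset_matrix(m, cells = which(m$cell_meta$cell_line == "CL1"))
  sig <- gene_signature("p1", small_sim()$truth$program_genes$P1)
  rk <- aucell_rankings(ml, seed = 5)
  t10 <- activity_threshold(ml, sig, n_repeats = 10, seed = 5, rankings = rk)
  t30 <- activity_threshold(ml, sig, n_repeats = 30, seed = 5, rankings = rk)
  expect_equal(as.numeric(t10), max(attr(t10, "putative")))
  expect_gte(as.numeric(t30), as.numeric(t10))
  # determinism
  t10b <- activity_threshold(ml, sig, n_repeats = 10, seed = 5, rankings = rk)
  expect_equal(as.numeric(t10), as.numeric(t10b))
})

test_that("planted-program cells are called active, others are not", {
  sim <- small_sim()
  m <- small_lognorm()
  ml <- subset_matrix(m, cells = which(m$cell_meta$cell_line == "CL1"))
  sig <- gene_signature("p1", sim$truth$program_genes$P1)
  act <- score_activity(ml, sig, seed = 9)
  planted <- ml$cell_meta$cluster %in% sim$truth$active_clusters$P1
  expect_gte(mean(act$active[planted]), 0.9)
  expect_lte(mean(act$active[!planted]), 0.1)
  expect_identical(act$active, act$scores > act$threshold)
})

test_that("module score is near zero under the null and linear in shifts", {
  set.seed(17)
  v <- matrix(rnorm(500 * 60, 3, 0.5), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("c%02d", 1:60)))
  v <- pmax(v, 0)
  m <- expression_matrix(v, data.frame(cell_id = colnames(v), cell_line = "L",
                                       cluster = "A"), layer = "lognorm")
  sig <- gene_signature("s", sample(rownames(v), 30))
  ms <- suppressWarnings(
    module_score(m, sig, n_bins = 5, ctrl_per_gene = 20, seed = 2))
  expect_lt(abs(mean(ms)), 0.1)
  # shift the signature genes by +delta in one cell: its score rises by delta
  delta <- 0.7
  v2 <- v
  v2[sig$genes, "c01"] <- v2[sig$genes, "c01"] + delta
  m2 <- expression_matrix(v2, m$cell_meta, layer = "lognorm")
  # same bins/controls would shift slightly; compare score difference loosely
  ms2 <- suppressWarnings(
    module_score(m2, sig, n_bins = 5, ctrl_per_gene = 20, seed = 2))
  expect_equal(unname(ms2["c01"] - ms["c01"]), delta, tolerance = 0.05)
})

test_that("cell-cycle assignment recovers planted phases and breaks ties by priority", {
  phases <- c("G0", "G1", "S", "G2M")
  set.seed(23)
  n_cells <- 120
  true_phase <- sample(phases, n_cells, replace = TRUE)
  v <- matrix(rnorm(320 * n_cells, 2, 0.4), nrow = 320,
              dimnames = list(sprintf("g%03d", 1:320),
                              sprintf("c%03d", 1:n_cells)))
  phase_sigs <- list()
  for (i in seq_along(phases)) {
    genes <- sprintf("g%03d", ((i - 1) * 20 + 1):(i * 20))
    phase_sigs[[phases[i]]] <- gene_signature(phases[i], genes)
    v[genes, true_phase == phases[i]] <-
      v[genes, true_phase == phases[i]] + 1.5
  }
  v <- pmax(v, 0)
  m <- expression_matrix(v, data.frame(cell_id = colnames(v), cell_line = "L",
                                       cluster = "A"), layer = "lognorm")
  got <- suppressWarnings(assign_cell_cycle(m, phase_sigs, seed = 3, n_bins = 5,
                                            ctrl_per_gene = 10))
  expect_gte(mean(got == true_phase), 0.9)
  expect_error(assign_cell_cycle(m, phase_sigs[c("G1", "S", "G2M")], seed = 1),
               "G0")
  # all-equal scores: the tie goes to the first phase in priority order
  flat <- matrix(1, nrow = 320, ncol = 2,
                 dimnames = list(rownames(v), c("x1", "x2")))
  mf <- expression_matrix(flat, data.frame(cell_id = c("x1", "x2"),
                                           cell_line = "L", cluster = "A"),
                          layer = "lognorm")
  lab <- suppressWarnings(assign_cell_cycle(mf, phase_sigs, seed = 1, n_bins = 2,
                                            ctrl_per_gene = 5))
  expect_true(all(lab == "G0"))
})

test_that("ssgsea is maximal for top placement and antisymmetric at alpha 0", {
  vals <- setNames(10:1, letters[1:10])
  top <- gene_signature("t", letters[1:3])
  bottom <- gene_signature("b", letters[8:10])
  s_top <- ssgsea(vals, top, alpha = 0.25)
  s_bot <- ssgsea(vals, bottom, alpha = 0.25)
  expect_gt(s_top, s_bot)
  # maximal over random placements of a 3-gene set
  for (i in 1:25) {
    set.seed(i)
    s <- ssgsea(vals, gene_signature("r", sample(letters[1:10], 3)), 0.25)
    expect_lte(s, s_top)
  }
  # alpha = 0: reversing the ranking negates the score
  rev_vals <- setNames(1:10, letters[1:10])
  expect_equal(ssgsea(vals, top, alpha = 0), -ssgsea(rev_vals, top, alpha = 0))
  expect_error(ssgsea(vals, gene_signature("all", letters[1:10])), "universe")
})

test_that("ssgsea matches a position-by-position hand enumeration", {
  vals <- setNames(10:1, letters[1:10])
  sig <- gene_signature("t", letters[1:3])
  # ranks N..1 descending; weights rnk^0.25 for in-set positions 1..3
  w <- (10:8)^0.25
  cdf_in <- cumsum(c(w[1], w[2], w[3], rep(0, 7))) / sum(w)
  cdf_out <- cumsum(c(0, 0, 0, rep(1, 7))) / 7
  expect_equal(ssgsea(vals, sig, alpha = 0.25), sum(cdf_in - cdf_out))
})

test_that("gsea is deterministic, signed consistently, and matches fgsea", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:300)
  stats_v <- sort(rnorm(300, 0, 1.5), decreasing = TRUE)
  rl <- ranked_gene_list(genes, stats_v, resort = FALSE)
  sig <- gene_signature("top", genes[1:20])
  a <- gsea(rl, sig, n_perm = 500, seed = 7)
  b <- gsea(rl, sig, n_perm = 500, seed = 7)
  expect_identical(a, b)
  expect_gt(a$es, 0)
  expect_lte(a$es, 1)
  expect_equal(sign(a$nes), sign(a$es))
  expect_lt(a$p, 0.05)
  # independent oracle: fgsea on the same preranked input
  ref <- suppressWarnings(fgsea::fgseaSimple(
    pathways = list(top = sig$genes),
    stats = setNames(stats_v, genes), nperm = 2000, scoreType = "std"))
  expect_equal(a$es, ref$ES, tolerance = 1e-6)
  expect_equal(a$nes, ref$NES, tolerance = 0.15)
})

test_that("effect-size and rank-sum statistics match hand calculations", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # translation: shifting x by s moves d by s / pooled sd (= 1 here)
  expect_equal(cohens_d(c(1, 2, 3) + 2, c(3, 4, 5)), 0)
  expect_error(cohens_d(c(1, 1), c(2, 2)), "zero")
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1)
  # exchanging the groups flips one-sided p-values
  g <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")$p
  l <- wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3), "greater")$p
  expect_equal(g, l)
  # identical samples sit at the null center
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 0.9)
})
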