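# Variable genes, differential mean vectors, Spearman grouping,
# supercluster consensus signatures

test_that("variable-gene selection ranks planted overdispersed genes on top", {
  set.seed(41)
  n_genes <- 500; n_cells <- 300
  mu <- rlnorm(n_genes, 0, 0.5)
  counts <- matrix(rpois(n_genes * n_cells, mu), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:n_cells)))
  hot <- sprintf("g%03d", 1:20)          # strongly overdispersed genes
  counts[1:20, ] <- matrix(rnbinom(20 * n_cells, size = 0.1,
                                   mu = mu[1:20] * 2), nrow = 20)
  counts["g021", ] <- 5                  # constant gene
  meta <- data.frame(cell_id = colnames(counts), cell_line = "L",
                     cluster = "A")
  m <- lognormalize(expression_matrix(counts, meta, layer = "counts"))
  top <- variable_genes(m, n = 50)
  expect_gte(length(intersect(top, hot)), 18)
  expect_false("g021" %in% top)
  expect_warning(all_g <- variable_genes(m, n = 1000), "exceeds")
  expect_setequal(all_g, rownames(counts))
})

test_that("shared variable genes is a sorted intersection with error on empty", {
  expect_identical(shared_variable_genes(list(c("b", "a", "c"),
                                              c("c", "b", "d"))),
                   c("b", "c"))
  expect_identical(shared_variable_genes(list(c("a", "b"), c("b", "a"))),
                   c("a", "b"))
  expect_error(shared_variable_genes(list(c("a"), c("b"))), "empty")
  expect_error(shared_variable_genes(list(c("a"))), ">= 2")
})

test_that("differential mean vector contrasts a cluster with its line", {
  sim <- small_sim()
  m <- small_lognorm()
  ml <- subset_matrix(m, cells = which(m$cell_meta$cell_line == "CL1"))
  genes <- rownames(ml$values)[1:200]
  v <- differential_mean_vector(ml, "CL1_C1", genes)
  expect_length(v, 200)
  expect_identical(names(v), genes)
  prog_in <- intersect(sim$truth$program_genes$P1, genes)
  if (length(prog_in) > 3) expect_true(all(v[prog_in] > 0))
  expect_error(differential_mean_vector(ml, "missing", genes), "empty")
})

test_that("spearman correlation matches a midrank oracle on short vectors", {
  expect_equal(correlation_matrix(list(a = c(1, 2, 3, 4),
                                       b = c(1, 3, 2, 4)))["a", "b"], 0.8)
  v <- c(2, 7, 1, 9)
  cm <- correlation_matrix(list(x = v, y = -v))   # rank-reversed partner
  expect_equal(cm["x", "y"], -1)
  expect_equal(diag(cm), c(x = 1, y = 1))
  spearman_oracle <- function(x, y) {
    midrank <- function(z) vapply(z, function(zi)
      sum(z < zi) + (sum(z == zi) + 1) / 2, numeric(1))
    rx <- midrank(x); ry <- midrank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  for (i in 1:20) {
    set.seed(i)
    len <- sample(4:10, 1)
    x <- sample(1:5, len, replace = TRUE)   # ties exercised
    y <- rnorm(len)
    if (var(x) == 0) x[1] <- x[1] + 1
    got <- correlation_matrix(list(x = as.numeric(x), y = y))["x", "y"]
    expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(correlation_matrix(list(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant")
})

test_that("block-structured correlation yields the planted superclusters", {
  # two perfect blocks, each with RACs from three lines, plus noise clusters
  set.seed(51)
  base1 <- rnorm(30); base2 <- rnorm(30)
  vectors <- list()
  lines <- c()
  for (ln in c("CL1", "CL2", "CL3")) {
    vectors[[paste0(ln, "_C1")]] <- base1 + rnorm(30, 0, 0.05)
    vectors[[paste0(ln, "_C2")]] <- base2 + rnorm(30, 0, 0.05)
    vectors[[paste0(ln, "_C3")]] <- rnorm(30)
    lines <- c(lines, rep(ln, 3))
  }
  names(lines) <- names(vectors)
  rac <- setNames(grepl("_C[12]$", names(vectors)), names(vectors))
  corr <- correlation_matrix(vectors)
  g <- group_superclusters(corr, rac, lines, min_lines = 2, cut = 0.7)
  asg <- g$assignment[g$assignment$is_rac, ]
  planted <- ifelse(grepl("_C1$", asg$cluster_id), "B1", "B2")
  expect_equal(ari(planted, asg$supercluster), 1)
  # non-RAC clusters are never assigned
  expect_true(all(is.na(
    g$assignment$supercluster[!g$assignment$is_rac])))
  # permuting input order leaves the assignment invariant
  perm <- sample(length(vectors))
  g2 <- group_superclusters(corr[perm, perm], rac[perm], lines[perm],
                            min_lines = 2, cut = 0.7)
  expect_equal(g2$assignment[order(g2$assignment$cluster_id), ],
               g$assignment[order(g$assignment$cluster_id), ],
               ignore_attr = TRUE)
})

test_that("uncorrelated clusters form no superclusters", {
  set.seed(61)
  vectors <- lapply(1:6, function(i) rnorm(40))
  names(vectors) <- paste0(rep(c("CL1", "CL2"), each = 3), "_C", rep(1:3, 2))
  lines <- setNames(rep(c("CL1", "CL2"), each = 3), names(vectors))
  rac <- setNames(rep(TRUE, 6), names(vectors))
  corr <- correlation_matrix(vectors)
  expect_warning(
    g <- group_superclusters(corr, rac, lines, min_lines = 2, cut = 0.2),
    "no group")
  expect_true(all(is.na(g$assignment$supercluster)))
})

test_that("min_lines controls whether a supercluster must span all lines", {
  # block shared by two of three lines only
  set.seed(71)
  base <- rnorm(30)
  vectors <- list(CL1_C1 = base + rnorm(30, 0, 0.05),
                  CL2_C1 = base + rnorm(30, 0, 0.05),
                  CL1_C2 = rnorm(30), CL2_C2 = rnorm(30), CL3_C1 = rnorm(30))
  lines <- setNames(sub("_C.*", "", names(vectors)), names(vectors))
  rac <- setNames(c(TRUE, TRUE, FALSE, FALSE, TRUE), names(vectors))
  corr <- correlation_matrix(vectors)
  g2 <- group_superclusters(corr, rac, lines, min_lines = 2, cut = 0.7)
  expect_identical(
    sort(g2$assignment$cluster_id[!is.na(g2$assignment$supercluster)]),
    c("CL1_C1", "CL2_C1"))
  expect_warning(
    g3 <- group_superclusters(corr, rac, lines, min_lines = 3, cut = 0.7),
    "no group")
  expect_true(all(is.na(g3$assignment$supercluster)))
})

test_that("supercluster consensus recovers planted program genes", {
  sim <- small_sim()
  m <- small_lognorm()
  truth_active <- unlist(sim$truth$active_clusters)
  per_line <- lapply(unique(m$cell_meta$cell_line), function(ln)
    subset_matrix(m, cells = which(m$cell_meta$cell_line == ln)))
  names(per_line) <- unique(m$cell_meta$cell_line)
  de <- lapply(unlist(sim$truth$active_clusters$P1), function(cl) {
    ln <- sub("_C.*", "", cl)
    ml <- per_line[[ln]]
    ga <- ml$cell_meta$cell_id[ml$cell_meta$cluster == cl]
    gb <- ml$cell_meta$cell_id[!ml$cell_meta$cluster %in% truth_active]
    differential_expression(ml, ga, gb)
  })
  cs <- supercluster_signature(de, "up", universe_size = nrow(m$values))
  recall <- length(intersect(cs$genes, sim$truth$program_genes$P1)) /
    length(sim$truth$program_genes$P1)
  expect_gte(recall, 0.8)
  # the down direction of the same lists yields a different (near-empty) set
  down <- suppressWarnings(
    supercluster_signature(de, "down", universe_size = nrow(m$values)))
  expect_lte(length(intersect(down$genes, cs$genes)), 0)
})
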