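# Differential expression, robust rank aggregation, consensus building

de_matrix <- function(values_a, values_b) {
  # one interesting gene plus filler genes so groups have >= 3 cells
  n <- length(values_a)
  v <- rbind(gene1 = c(values_a, values_b),
             filler1 = rep(1, 2 * n), filler2 = rep(2, 2 * n))
  colnames(v) <- sprintf("c%d", seq_len(2 * n))
  expression_matrix(v, data.frame(cell_id = colnames(v), cell_line = "L",
                                  cluster = rep(c("A", "B"), each = n)),
                    layer = "lognorm", norm = list(log_base = exp(1)))
}

test_that("differential expression: identical groups give lfc 0 and p 1", {
  m <- de_matrix(c(1, 2, 3), c(1, 2, 3))
  de <- differential_expression(m, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(de$log2fc[de$gene_id == "gene1"], 0)
  expect_equal(de$p[de$gene_id == "gene1"], 1)
})

test_that("differential expression matches the exact rank-sum enumeration", {
  m <- de_matrix(c(1, 2, 3), c(4, 5, 6))
  de <- differential_expression(m, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(de$p[de$gene_id == "gene1"], 0.1)   # 2/C(6,3) both tails
  expect_lt(de$log2fc[de$gene_id == "gene1"], 0)   # group A is lower
  expect_error(differential_expression(m, paste0("c", 1:3), paste0("c", 3:6)),
               "overlap")
  expect_error(differential_expression(m, paste0("c", 1:2), paste0("c", 4:6)),
               ">= 3")
})

test_that("planted fold-change genes outrank background in DE", {
  sim <- small_sim()
  m <- small_lognorm()
  meta <- m$cell_meta
  l1 <- meta$cell_line == "CL1"
  ga <- meta$cell_id[l1 & meta$cluster %in% sim$truth$active_clusters$P1]
  gb <- meta$cell_id[l1 & !meta$cluster %in% unlist(sim$truth$active_clusters)]
  de <- differential_expression(subset_matrix(m, cells = which(l1)), ga, gb)
  prog <- sim$truth$program_genes$P1
  top <- de$gene_id[seq_along(prog)]
  expect_gte(length(intersect(top, prog)) / length(prog), 0.95)
})

test_that("up/down filters use strict thresholds and keep order", {
  rl <- ranked_gene_list(c("a", "b", "c", "d"),
                         c(2, 0, 1, -1),
                         c(0.001, 0.001, 0.01, 0.001),
                         c(0.01, 0.01, 0.05, 0.01))
  up <- filter_up(rl)
  expect_identical(up$gene_id, "a")        # b: lfc == 0 out; c: p_adj == 0.05 out
  down <- filter_down(rl)
  expect_identical(down$gene_id, "d")
  empty <- filter_up(rl[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("rra rho matches hand-computed binomial tails", {
  expect_equal(rra_rho(0.2, 1), 0.2)
  expect_equal(rra_rho(c(0.01, 0.01), 2), 1e-4)    # min(1 - 0.99^2, 1e-4)
  expect_equal(rra_rho(c(1, 1, 1), 3), 1)
  expect_error(rra_rho(c(0, 0.5), 2), "\\(0, 1\\]")
  expect_error(rra_rho(c(0.1, 0.2, 0.3), 2), "more ranks")
})

test_that("rra rho agrees with a Monte-Carlo order-statistic oracle", {
  cases <- list(list(r = c(0.2, 0.5), m = 3),
                list(r = c(0.1, 0.25, 0.4, 0.8), m = 6),
                list(r = c(0.05, 0.3, 0.6, 0.9), m = 4),
                list(r = 0.3, m = 5))
  B <- 2e5
  for (cs in cases) {
    set.seed(7)
    U <- matrix(runif(B * cs$m), ncol = cs$m)
    r <- sort(cs$r)
    beta_mc <- vapply(seq_along(r), function(j)
      mean(rowSums(U <= r[j]) >= j), numeric(1))
    se <- sqrt(pmax(beta_mc * (1 - beta_mc), 1e-12) / B)
    beta_exact <- vapply(seq_along(r), function(j)
      pbinom(j - 1, cs$m, r[j], lower.tail = FALSE), numeric(1))
    expect_true(all(abs(beta_exact - beta_mc) <= 3 * se + 1e-8))
    expect_equal(rra_rho(cs$r, cs$m), min(beta_exact))
  }
})

test_that("rra aggregation retains unanimous top genes and drops median ones", {
  genes <- sprintf("g%04d", 1:1000)
  # g0001 first and g0500 exactly at the median of every list; the rest shuffled
  lists <- lapply(1:6, function(i) {
    set.seed(i)
    rest <- sample(setdiff(genes, c("g0001", "g0500")))
    ids <- c("g0001", rest[1:498], "g0500", rest[499:998])
    ranked_gene_list(ids, seq(4, 0.1, length.out = 1000), resort = FALSE)
  })
  agg <- rra_aggregate(lists)
  expect_true("g0001" %in% agg$genes)
  expect_false("g0500" %in% agg$genes)
  # invariance to list input order
  agg_rev <- rra_aggregate(rev(lists))
  expect_identical(sort(agg$genes), sort(agg_rev$genes))
})

test_that("rra recovers the planted consensus with few background genes", {
  rl <- simulate_ranked_lists(n_lists = 6, list_len = 1000, n_consensus = 50,
                              consensus_top_frac = 0.05, seed = 13)
  agg <- rra_aggregate(rl$lists)
  recall <- length(intersect(agg$genes, rl$truth$consensus_genes)) / 50
  fpr <- length(setdiff(agg$genes, rl$truth$consensus_genes)) / 950
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("majority-vote consensus respects the support boundary", {
  sigs <- lapply(1:9, function(i) {
    genes <- c("always", if (i <= 5) "five", if (i <= 4) "four", paste0("u", i))
    gene_signature(paste0("s", i), genes)
  })
  cons <- consensus_majority(sigs, min_support = 5)
  expect_true(all(c("always", "five") %in% cons$genes))
  expect_false("four" %in% cons$genes)
  uni <- consensus_majority(sigs, min_support = 1)
  expect_identical(sort(uni$genes),
                   sort(unique(unlist(lapply(sigs, `[[`, "genes")))))
  expect_warning(out <- consensus_majority(sigs[1:3], min_support = 5),
                 "exceeds")
  expect_length(out$genes, 0)
})

test_that("top-n extraction obeys list length and n = 0", {
  rl <- ranked_gene_list(sprintf("g%03d", 1:500), 500:1)
  expect_length(top_n_signature(rl, 200)$genes, 200)
  expect_identical(top_n_signature(rl, 200)$genes, sprintf("g%03d", 1:200))
  short <- ranked_gene_list(sprintf("g%03d", 1:50), 50:1)
  expect_length(top_n_signature(short, 200)$genes, 50)
  expect_warning(empty <- top_n_signature(rl, 0), "empty")
  expect_length(empty$genes, 0)
})

test_that("ortholog mapping uses set semantics and reports unmapped genes", {
  sig <- gene_signature("yeast", paste0("y", 1:10))
  ortho <- data.frame(source = c("y1", "y1", "y2", "y3", "y4", "y5", "y6", "y7"),
                      target = c("HA", "HB", "HB", "HC", "HD", "HE", "HF", "HG"))
  out <- map_orthologs(sig, ortho)
  expect_identical(out$genes, sort(unique(ortho$target)))  # 7 distinct targets
  expect_equal(attr(out, "unmapped"), 3)
  expect_error(map_orthologs(sig, data.frame(source = "z", target = "H")),
               "unmapped")
})
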