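# Shared fixtures, built in code and memoised so expensive simulations run
# once per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small multi-line simulation with two planted programs (reduced sizes for
# unit tests; the acceptance suite runs the full study conditions)
small_sim <- function() memo("small_sim", {
  simulate_cell_lines(n_lines = 3, clusters_per_line = 4,
                      cells_per_cluster = 80, n_genes = 600,
                      program_size = 40, fold = 4, n_programs = 2,
                      seed = 42)
})

small_lognorm <- function() memo("small_lognorm", lognormalize(small_sim()$matrix))

# deterministic tiny matrix: 10 genes x 6 cells, two clusters
tiny_matrix <- function(layer = "lognorm") {
  v <- matrix(0, nrow = 10, ncol = 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("c%d", 1:6)))
  set.seed(99)
  v[] <- rpois(60, 3)
  meta <- data.frame(cell_id = colnames(v), cell_line = "L1",
                     cluster = rep(c("A", "B"), each = 3),
                     stringsAsFactors = FALSE)
  if (layer == "lognorm") {
    lognormalize(expression_matrix(v, meta, layer = "counts"))
  } else {
    expression_matrix(v, meta, layer = "counts")
  }
}

# single-cell-expression column with a fully determined ranking:
# gene g001 most expressed, g100 least
ladder_matrix <- function(n_genes = 100) {
  v <- matrix(as.numeric(n_genes:1), ncol = 1,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), "c1"))
  expression_matrix(v, data.frame(cell_id = "c1", cell_line = "L",
                                  cluster = "X"), layer = "lognorm")
}

# adjusted Rand index between two labelings (closed form on the pair counts)
ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
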