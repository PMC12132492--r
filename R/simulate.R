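#' Planted ground truth of a simulated dataset
#'
#' Every generator returns its dataset together with a `SimTruth` so
#' downstream stages can be tested against known answers: which clusters
#' carry a planted program, which genes form it, the fold-change, the
#' consensus genes planted in ranked lists, or the planted log hazard
#' ratio.
#'
#' @param ... Named truth fields.
#' @return A `SimTruth` (named list).
#' @export
sim_truth <- function(...) structure(list(...), class = "SimTruth")

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a SimTruth as a JSON sidecar
#' @param truth `SimTruth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  writeLines(jsonlite::toJSON(unclass(truth), auto_unbox = TRUE,
                              null = "null", digits = NA), path)
  invisible(path)
}

#' Simulate multi-cell-line clustered single-cell counts with planted
#' resistance programs
#'
#' Counts are negative binomial with log-normal gene baseline means; every
#' cell line has `clusters_per_line` pre-assigned clusters of
#' `cells_per_cluster` cells. `n_programs` disjoint gene programs of
#' `program_size` genes are planted: program p multiplies its genes' means
#' by `fold` in one designated active cluster per cell line, emulating a
#' shared resistance transcriptional state recurring across lines. Each
#' program also has a target drug class concentrated (about 85-90% of its
#' treated cells) in its active clusters; other treated cells draw from
#' background classes. About 80% of cells are treated; untreated cells
#' carry no drug label. Identical seed gives bit-identical output.
#'
#' @param n_lines Number of cell lines (default 3).
#' @param clusters_per_line Clusters per line (default 8).
#' @param cells_per_cluster Cells per cluster (default 200).
#' @param n_genes Genes (default 2000).
#' @param program_size Genes per planted program (default 100).
#' @param fold Multiplicative mean shift in active clusters (default 4;
#'   `fold = 1` plants no signal).
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion;
#'   default 0.3).
#' @param n_programs Number of planted programs (default 2).
#' @param treated_frac Fraction of treated cells (default 0.8).
#' @param seed Integer seed.
#' @return List with `matrix` (`ExpressionMatrix`, counts layer) and
#'   `truth` (`SimTruth` with `active_clusters` and `program_genes` as
#'   per-program lists, `target_class` per program, `fold`, `seed`).
#' @export
simulate_cell_lines <- function(n_lines = 3, clusters_per_line = 8,
                                cells_per_cluster = 200, n_genes = 2000,
                                program_size = 100, fold = 4,
                                dispersion = 0.3, n_programs = 2,
                                treated_frac = 0.8, seed = 1) {
  if (min(n_lines, clusters_per_line, cells_per_cluster, n_genes,
          program_size) < 1) stopf("all sizes must be >= 1")
  if (fold < 1) stopf("fold must be >= 1")
  if (n_programs * program_size > n_genes)
    stopf("program genes (%d x %d) exceed n_genes (%d)",
          n_programs, program_size, n_genes)
  if (n_programs > clusters_per_line)
    stopf("need at least one cluster per program per line")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    base_mu <- stats::rlnorm(n_genes, meanlog = -0.5, sdlog = 1)
    prog_idx <- split(sample.int(n_genes, n_programs * program_size),
                      rep(seq_len(n_programs), each = program_size))
    program_genes <- lapply(prog_idx, function(i) genes[i])
    names(program_genes) <- paste0("P", seq_len(n_programs))
    lines <- paste0("CL", seq_len(n_lines))
    active <- lapply(seq_len(n_programs), function(p)
      paste0(lines, "_C", p))
    names(active) <- names(program_genes)
    bg_classes <- paste0("classBG", 1:3)
    target_class <- stats::setNames(paste0("classP", seq_len(n_programs)),
                                    names(program_genes))
    n_cells_line <- clusters_per_line * cells_per_cluster
    size <- 1 / dispersion
    cols <- list(); meta <- list()
    for (l in seq_len(n_lines)) {
      for (cc in seq_len(clusters_per_line)) {
        cl_id <- paste0(lines[l], "_C", cc)
        mu <- base_mu
        prog_here <- if (cc <= n_programs) cc else 0L
        if (prog_here > 0) mu[prog_idx[[prog_here]]] <- mu[prog_idx[[prog_here]]] * fold
        cnt <- matrix(stats::rnbinom(n_genes * cells_per_cluster,
                                     size = size, mu = mu),
                      nrow = n_genes)
        cols[[cl_id]] <- cnt
        treated <- stats::runif(cells_per_cluster) < treated_frac
        dc <- rep(NA_character_, cells_per_cluster)
        if (prog_here > 0) {
          tgt <- stats::runif(cells_per_cluster) < 0.9
          dc[treated & tgt] <- target_class[prog_here]
          dc[treated & !tgt] <- sample(bg_classes, sum(treated & !tgt),
                                       replace = TRUE)
        } else {
          # small leak of target classes outside active clusters keeps the
          # >= 80% concentration property while staying realistic
          leak <- stats::runif(cells_per_cluster) < 0.02
          dc[treated & leak] <- sample(unname(target_class),
                                       sum(treated & leak), replace = TRUE)
          dc[treated & !leak] <- sample(bg_classes, sum(treated & !leak),
                                        replace = TRUE)
        }
        meta[[cl_id]] <- data.frame(
          cell_line = lines[l], cluster = cl_id, treated = treated,
          drug = ifelse(is.na(dc), NA_character_, paste0(dc, "_drug1")),
          drug_class = dc, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
    cm <- do.call(rbind, meta)
    cm$cell_id <- colnames(counts)
    m <- expression_matrix(counts, cm, layer = "counts")
    truth <- sim_truth(active_clusters = active,
                       program_genes = program_genes,
                       target_class = as.list(target_class),
                       fold = fold, dispersion = dispersion, seed = seed)
    list(matrix = m, truth = truth)
  })
}

#' Simulate ranked gene lists with a planted consensus subset
#'
#' Each list is a permutation of a shared gene universe with strictly
#' decreasing log2 fold-change scores. The planted consensus genes are
#' placed uniformly at random within the top `consensus_top_frac` of every
#' list; remaining genes fill the other positions uniformly.
#'
#' @param n_lists Number of lists (default 6).
#' @param list_len Universe size (default 1000).
#' @param n_consensus Planted consensus genes (default 50); must not
#'   exceed `list_len * consensus_top_frac`.
#' @param consensus_top_frac Fraction of the top reserved for the
#'   consensus placement (default 0.05); 1 makes consensus genes
#'   indistinguishable from background.
#' @param seed Integer seed.
#' @param universe Optional gene-id vector of length `list_len` to use as
#'   the shared universe (default: generated ids).
#' @param consensus_genes Optional explicit consensus subset of the
#'   universe (overrides `n_consensus`), so ranked lists can be made
#'   coherent with a simulated expression matrix's planted program.
#' @return List with `lists` (list of `RankedGeneList`) and `truth`
#'   (`SimTruth` with `consensus_genes`).
#' @export
simulate_ranked_lists <- function(n_lists = 6, list_len = 1000,
                                  n_consensus = 50,
                                  consensus_top_frac = 0.05, seed = 1,
                                  universe = NULL, consensus_genes = NULL) {
  if (!is.null(universe) && length(universe) != list_len)
    stopf("universe length (%d) != list_len (%d)", length(universe), list_len)
  if (!is.null(consensus_genes)) {
    if (!is.null(universe) && !all(consensus_genes %in% universe))
      stopf("consensus_genes not all in universe")
    n_consensus <- length(consensus_genes)
  }
  top_k <- floor(list_len * consensus_top_frac)
  if (n_consensus > top_k)
    stopf("n_consensus (%d) exceeds list_len * consensus_top_frac (%d)",
          n_consensus, top_k)
  with_seed(seed, {
    genes <- universe %||% sprintf("g%04d", seq_len(list_len))
    consensus <- sort(consensus_genes %||% sample(genes, n_consensus))
    background <- setdiff(genes, consensus)
    lfc <- 4 * (list_len:1) / list_len        # strictly decreasing
    p <- pmin(seq_len(list_len) / list_len, 1)
    lists <- lapply(seq_len(n_lists), function(i) {
      pos_c <- sample(top_k, n_consensus)
      ids <- character(list_len)
      ids[pos_c] <- sample(consensus)
      ids[ids == ""] <- sample(background)
      ranked_gene_list(ids, lfc, p, pmin(p * 2, 1), resort = FALSE)
    })
    list(lists = lists,
         truth = sim_truth(consensus_genes = consensus,
                           consensus_top_frac = consensus_top_frac,
                           seed = seed))
  })
}

#' Simulate a bulk survival cohort with a planted signature effect
#'
#' Bulk expression in log-normalized units: each sample has a latent
#' signature activity `a_s ~ N(0, 1)` that shifts every signature gene by
#' `a_s` on top of its baseline; non-signature genes are independent noise.
#' Event times are exponential with hazard `h0 * exp(beta * a_s)`;
#' censoring is an independent exponential whose rate is solved so the
#' expected censored fraction equals `censor_rate`. Covariates age, sex
#' and purity are generated independently of the hazard. A draw in which
#' every sample is censored is regenerated (up to 10 retries).
#'
#' @param n_samples Samples (default 500).
#' @param n_genes Universe size including the signature genes
#'   (default 1000).
#' @param signature `GeneSignature` whose genes carry the planted effect.
#' @param beta Planted log hazard ratio per unit activity (default 1).
#' @param censor_rate Expected censored fraction in `[0, 1)` (default 0.3).
#' @param baseline_hazard `h0` (default 0.1).
#' @param noise_sd Per-gene residual SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `matrix` (`ExpressionMatrix`, lognorm layer, samples
#'   as columns), `survival` (data.frame: sample_id, time, event, age,
#'   sex, purity) and `truth` (`SimTruth` with `survival_beta` and the
#'   latent `activity`).
#' @export
simulate_survival_cohort <- function(n_samples = 500, n_genes = 1000,
                                     signature, beta = 1, censor_rate = 0.3,
                                     baseline_hazard = 0.1, noise_sd = 0.5,
                                     seed = 1) {
  if (censor_rate < 0 || censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  sig_genes <- signature$genes
  if (length(sig_genes) >= n_genes)
    stopf("signature covers the whole universe")
  with_seed(seed, {
    genes <- c(sig_genes,
               sprintf("bg%04d", seq_len(n_genes - length(sig_genes))))
    samples <- sprintf("s%04d", seq_len(n_samples))
    a <- stats::rnorm(n_samples)
    base <- stats::runif(n_genes, 2, 8)
    x <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                nrow = n_genes) + base
    in_sig <- genes %in% sig_genes
    x[in_sig, ] <- x[in_sig, ] + rep(a, each = sum(in_sig))
    x <- pmax(x, 0)
    rownames(x) <- genes
    colnames(x) <- samples
    hz <- baseline_hazard * exp(beta * a)
    surv <- NULL
    for (try in seq_len(10)) {
      tt <- stats::rexp(n_samples, rate = hz)
      if (censor_rate == 0) {
        time <- tt; event <- rep(TRUE, n_samples)
      } else {
        lam <- stats::uniroot(
          function(loglam) mean(exp(loglam) / (exp(loglam) + hz)) - censor_rate,
          interval = c(-20, 20))$root
        cc <- stats::rexp(n_samples, rate = exp(lam))
        event <- tt <= cc
        time <- pmin(tt, cc)
      }
      if (any(event)) { surv <- list(time = time, event = event); break }
      warnf("all-censored draw; regenerating (try %d)", try)
    }
    if (is.null(surv)) stopf("all samples censored after 10 retries")
    survival_df <- data.frame(
      sample_id = samples, time = surv$time, event = surv$event,
      age = stats::runif(n_samples, 40, 80),
      sex = sample(c("F", "M"), n_samples, replace = TRUE),
      purity = stats::rbeta(n_samples, 5, 2), stringsAsFactors = FALSE)
    meta <- data.frame(cell_id = samples, cell_line = "cohort",
                       cluster = "bulk", stringsAsFactors = FALSE)
    m <- expression_matrix(x, meta, layer = "lognorm",
                           norm = list(scale = NA, log_base = exp(1)))
    list(matrix = m, survival = survival_df,
         truth = sim_truth(survival_beta = beta, censor_rate = censor_rate,
                           activity = stats::setNames(a, samples),
                           signature = signature$genes, seed = seed))
  })
}

#' Mean signature expression activity, z-scored across samples
#'
#' The simple activity measure paired with the survival simulator: the
#' mean log-normalized expression of the signature genes per sample,
#' z-scored across samples. Monotone in the planted signal.
#'
#' @param m `ExpressionMatrix` (lognorm layer).
#' @param sig `GeneSignature`.
#' @return Named numeric vector, one value per sample/cell.
#' @export
signature_activity <- function(m, sig) {
  present <- intersect(sig$genes, rownames(m$values))
  if (length(present) == 0) stopf("no signature gene present")
  v <- Matrix::colMeans(m$values[match(present, rownames(m$values)), ,
                                 drop = FALSE])
  stats::setNames(as.numeric(scale(v)), colnames(m$values))
}
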