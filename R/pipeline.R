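#' Pipeline run configuration
#'
#' Collects input paths and every tunable of the analysis with its default.
#' Defaults follow the documented conventions of each stage: QC bounds
#' 200/2500 features, gene filter 100 cells, scale 10000, AUCell top 5%
#' window, 10 expression bins, 95th percentile over 100 control repeats,
#' RAC thresholds OR > 1 and adjusted p < 0.05, 2000 variable genes, tree
#' cut 0.7, superclusters spanning >= 2 lines, ssGSEA alpha 0.25.
#'
#' @param counts_dir Directory with MTX counts + sidecars
#'   (see [read_expression_mtx()]).
#' @param ranked_lists Character vector of ranked-list TSV paths (>= 2)
#'   for the consensus signature stage, or NULL to skip.
#' @param collection_gmt Optional GMT path for the enrichment stage.
#' @param bulk_dir,survival_tsv Optional bulk cohort (MTX dir) and
#'   survival TSV for the clinical stage.
#' @param ... Tunable overrides (see Details in the source).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `RunConfig` list.
#' @export
run_config <- function(counts_dir, ranked_lists = NULL, collection_gmt = NULL,
                       bulk_dir = NULL, survival_tsv = NULL, seed = 1, ...) {
  defaults <- list(
    min_features = 200, max_features = 2500, min_cells = 100, scale = 10000,
    max_rank_fraction = 0.05, n_bins = 10, pct = 95, n_repeats = 100,
    or_min = 1, padj_max = 0.05, max_rank_p = 0.05,
    n_variable = 2000, cut = 0.7, min_lines = 2, alpha = 0.25)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0)
    stopf("unknown tunable(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  cfg <- c(list(counts_dir = counts_dir, ranked_lists = ranked_lists,
                collection_gmt = collection_gmt, bulk_dir = bulk_dir,
                survival_tsv = survival_tsv, seed = seed), defaults)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a RunConfig from a flat key=value file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' `ranked_lists` may be a comma-separated list of paths.
#'
#' @param path Config file path.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  named <- stats::setNames(as.list(vals), keys)
  num_keys <- c("min_features", "max_features", "min_cells", "scale",
                "max_rank_fraction", "n_bins", "pct", "n_repeats", "or_min",
                "padj_max", "max_rank_p", "n_variable", "cut", "min_lines",
                "alpha", "seed")
  for (k in intersect(names(named), num_keys)) named[[k]] <- as.numeric(named[[k]])
  if ("ranked_lists" %in% names(named))
    named$ranked_lists <- trimws(strsplit(named$ranked_lists, ",")[[1]])
  do.call(run_config, named)
}

write_config <- function(cfg, path) {
  flat <- lapply(unclass(cfg), function(v)
    if (is.null(v)) NULL else paste(v, collapse = ","))
  flat <- flat[!vapply(flat, is.null, logical(1))]
  writeLines(paste(names(flat), "=", unlist(flat)), path)
  invisible(path)
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

stage_done <- function(dir, files) all(file.exists(file.path(dir, files)))

#' Run the full resistance-state analysis pipeline
#'
#' Executes prep, signature, activity scoring + threshold, RAC calling,
#' supercluster grouping with consensus signatures, and — when the config
#' provides the inputs — enrichment and clinical stages, in dependency
#' order. Each stage writes its tables under `out_dir/<stage>/` and is
#' skipped when its outputs already exist (delete a stage directory, or
#' pass `force = TRUE`, to recompute it and everything downstream reads
#' from disk, so downstream stages regenerate from cached upstream
#' output). The config and a run log are serialized into `out_dir`.
#'
#' @param config A `RunConfig` from [run_config()] / [read_run_config()].
#' @param out_dir Output directory.
#' @param force Recompute all stages (default FALSE).
#' @return `out_dir`, invisibly; tables on disk.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.txt"))
  logf <- file(file.path(out_dir, "run.log"), open = "at")
  on.exit(close(logf))
  seed <- config$seed
  dirty <- force   # once a stage recomputes, everything downstream follows
  tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                               quote = FALSE, row.names = FALSE)

  # -- prep ------------------------------------------------------------
  prep_dir <- file.path(out_dir, "prep")
  if (dirty || !stage_done(prep_dir, "matrix.mtx")) {
    log_line(logf, "prep: reading %s", config$counts_dir)
    m <- read_expression_mtx(config$counts_dir)
    m <- filter_cells(m, config$min_features, config$max_features)
    m <- filter_genes(m, config$min_cells)
    m <- lognormalize(m, scale = config$scale)
    write_expression_mtx(m, prep_dir)
    log_line(logf, "prep: %d genes x %d cells after QC", nrow(m$values),
             ncol(m$values))
    dirty <- TRUE
  } else log_line(logf, "prep: cached")
  m <- read_expression_mtx(prep_dir)

  # -- signature -------------------------------------------------------
  sig_dir <- file.path(out_dir, "signature")
  if (!is.null(config$ranked_lists)) {
    if (dirty || !stage_done(sig_dir, "signature.gmt")) {
      lists <- lapply(config$ranked_lists, read_ranked_list)
      sig <- rra_aggregate(lists, max_rank_p = config$max_rank_p,
                           name = "resistance_signature")
      dir.create(sig_dir, showWarnings = FALSE)
      write_gene_sets(sig, file.path(sig_dir, "signature.gmt"))
      tsv(attr(sig, "table"), file.path(sig_dir, "rra_table.tsv"))
      log_line(logf, "signature: %d genes retained", length(sig$genes))
      dirty <- TRUE
    } else log_line(logf, "signature: cached")
    sig <- read_gene_sets(file.path(sig_dir, "signature.gmt"))[[1]]
  } else stopf("pipeline requires ranked_lists to build the signature")

  # -- score -----------------------------------------------------------
  score_dir <- file.path(out_dir, "score")
  if (dirty || !stage_done(score_dir, c("scores.tsv", "thresholds.tsv"))) {
    dir.create(score_dir, showWarnings = FALSE)
    per_line <- lapply(unique(m$cell_meta$cell_line), function(ln) {
      ml <- subset_matrix(m, cells = which(m$cell_meta$cell_line == ln))
      act <- score_activity(ml, sig,
                            max_rank_fraction = config$max_rank_fraction,
                            n_bins = config$n_bins, pct = config$pct,
                            n_repeats = config$n_repeats,
                            seed = derive_seed(seed, paste0("score_", ln)))
      log_line(logf, "score: %s threshold %.4f, %d/%d active", ln,
               act$threshold, sum(act$active), length(act$active))
      list(line = ln, act = act)
    })
    scores <- do.call(rbind, lapply(per_line, function(x)
      data.frame(cell_id = names(x$act$scores), cell_line = x$line,
                 signature = sig$name, score = as.numeric(x$act$scores),
                 active = x$act$active, stringsAsFactors = FALSE)))
    thr <- do.call(rbind, lapply(per_line, function(x)
      data.frame(cell_line = x$line, threshold = x$act$threshold,
                 pct = config$pct, n_repeats = config$n_repeats,
                 seed = x$act$seed, stringsAsFactors = FALSE)))
    tsv(scores, file.path(score_dir, "scores.tsv"))
    tsv(thr, file.path(score_dir, "thresholds.tsv"))
    dirty <- TRUE
  } else log_line(logf, "score: cached")
  scores <- utils::read.delim(file.path(score_dir, "scores.tsv"),
                              colClasses = c(cell_id = "character"))

  # -- rac -------------------------------------------------------------
  rac_dir <- file.path(out_dir, "rac")
  if (dirty || !stage_done(rac_dir, "rac_table.tsv")) {
    dir.create(rac_dir, showWarnings = FALSE)
    activity <- list(active = stats::setNames(scores$active, scores$cell_id))
    rt <- call_racs(activity, m$cell_meta, or_min = config$or_min,
                    padj_max = config$padj_max)
    write_rac_table(rt, file.path(rac_dir, "rac_table.tsv"))
    log_line(logf, "rac: %d/%d clusters called RAC", sum(rt$is_rac), nrow(rt))
    dirty <- TRUE
  } else log_line(logf, "rac: cached")
  rt <- utils::read.delim(file.path(rac_dir, "rac_table.tsv"),
                          colClasses = c(cluster_id = "character"))

  # -- supercluster ----------------------------------------------------
  sc_dir <- file.path(out_dir, "supercluster")
  if (dirty || !stage_done(sc_dir, "assignment.tsv")) {
    dir.create(sc_dir, showWarnings = FALSE)
    lines <- unique(m$cell_meta$cell_line)
    per_line_m <- lapply(lines, function(ln)
      subset_matrix(m, cells = which(m$cell_meta$cell_line == ln)))
    names(per_line_m) <- lines
    hvg <- lapply(per_line_m, variable_genes, n = config$n_variable)
    shared <- shared_variable_genes(hvg)
    log_line(logf, "supercluster: %d shared variable genes", length(shared))
    vectors <- list()
    for (ln in lines) {
      for (cl in sort(unique(per_line_m[[ln]]$cell_meta$cluster)))
        vectors[[cl]] <- differential_mean_vector(per_line_m[[ln]], cl, shared)
    }
    corr <- correlation_matrix(vectors)
    rac_flags <- stats::setNames(rt$is_rac, rt$cluster_id)
    cls_line <- stats::setNames(rt$cell_line, rt$cluster_id)
    grouping <- group_superclusters(corr, rac_flags, cls_line,
                                    min_lines = config$min_lines,
                                    cut = config$cut)
    tsv(grouping$assignment, file.path(sc_dir, "assignment.tsv"))
    utils::write.table(round(corr, 6), file.path(sc_dir, "correlation.tsv"),
                       sep = "\t", quote = FALSE)
    writeLines(jsonlite::toJSON(list(merge = grouping$tree$merge,
                                     height = grouping$tree$height,
                                     labels = grouping$tree$labels,
                                     cut = config$cut), digits = NA),
               file.path(sc_dir, "linkage.json"))
    # consensus signature per supercluster from component-RAC DE lists
    sc_ids <- sort(stats::na.omit(unique(grouping$assignment$supercluster)))
    sigs <- list()
    for (sc in sc_ids) {
      members <- grouping$assignment$cluster_id[
        grouping$assignment$supercluster %in% sc]
      de <- lapply(members, function(cl) {
        ln <- cls_line[[cl]]
        ml <- per_line_m[[ln]]
        rac_cl <- rt$cluster_id[rt$is_rac & rt$cell_line == ln]
        ga <- ml$cell_meta$cell_id[ml$cell_meta$cluster == cl]
        gb <- ml$cell_meta$cell_id[!ml$cell_meta$cluster %in% rac_cl]
        differential_expression(ml, ga, gb)
      })
      sigs[[sc]] <- supercluster_signature(de, "up", name = sc)
      log_line(logf, "supercluster: %s consensus %d genes", sc,
               length(sigs[[sc]]$genes))
    }
    if (length(sigs) > 0)
      write_gene_sets(sigs, file.path(sc_dir, "consensus_signatures.gmt"))
    dirty <- TRUE
  } else log_line(logf, "supercluster: cached")

  # -- enrichment ------------------------------------------------------
  if (!is.null(config$collection_gmt) &&
      file.exists(file.path(sc_dir, "consensus_signatures.gmt"))) {
    enr_dir <- file.path(out_dir, "enrichment")
    if (dirty || !stage_done(enr_dir, "enrichment.tsv")) {
      dir.create(enr_dir, showWarnings = FALSE)
      collection <- read_gene_sets(config$collection_gmt)
      sigs <- read_gene_sets(file.path(sc_dir, "consensus_signatures.gmt"))
      res <- do.call(rbind, lapply(sigs, function(s) {
        r <- overrepresentation(s, collection, rownames(m$values))
        cbind(query = s$name, r)
      }))
      tsv(res, file.path(enr_dir, "enrichment.tsv"))
      log_line(logf, "enrichment: %d rows", nrow(res))
    } else log_line(logf, "enrichment: cached")
  }

  # -- clinical --------------------------------------------------------
  if (!is.null(config$bulk_dir) && !is.null(config$survival_tsv)) {
    cl_dir <- file.path(out_dir, "clinical")
    if (dirty || !stage_done(cl_dir, "cox.tsv")) {
      dir.create(cl_dir, showWarnings = FALSE)
      bulk <- read_expression_mtx(config$bulk_dir)
      surv <- read_survival(config$survival_tsv)
      ss <- vapply(seq_len(ncol(bulk$values)), function(j)
        ssgsea(stats::setNames(as.numeric(bulk$values[, j]),
                               rownames(bulk$values)),
               sig, alpha = config$alpha), numeric(1))
      surv$score <- as.numeric(scale(ss[match(surv$sample_id,
                                              colnames(bulk$values))]))
      fit <- cox_fit(surv)
      tsv(as.data.frame(fit), file.path(cl_dir, "cox.tsv"))
      grp <- km_median_split(stats::setNames(surv$score, surv$sample_id))
      tsv(data.frame(sample_id = names(grp), group = as.character(grp),
                     stringsAsFactors = FALSE),
          file.path(cl_dir, "km_groups.tsv"))
      log_line(logf, "clinical: signature HR %.3f",
               fit$hr[fit$covariate == "score"])
    } else log_line(logf, "clinical: cached")
  }
  invisible(out_dir)
}
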