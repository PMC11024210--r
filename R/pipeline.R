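#' Pipeline configuration
#'
#' A single flat, serializable configuration for the end-to-end run. All
#' defaults are the stage defaults: loess span 0.5 with a 3-SD cut, minimum
#' 200 detected genes, maximum 10\% mitochondrial counts, genes kept at >=
#' 10 cells, components kept above 1\% explained variance, marker-gate
#' validation at AUROC 0.7, one thousand bootstrapped trees on two thirds
#' of the cells, a 3-D MDS, and a skeleton of up to one hundred nodes.
#'
#' @param ... overrides of any default field (see the function body for
#'   the full schema); unknown fields are an error.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # stage toggles
    do_simulate = TRUE, do_qc = TRUE, do_cluster = TRUE, do_score = TRUE,
    do_order = FALSE, do_clones = FALSE,
    # simulation
    n_cells = 1000L, n_genes = 2000L, n_clusters = 6L,
    n_markers_per_cluster = 30L, marker_logfc = 2, libsize_mean = 2500,
    lowq_fraction = 0, doublet_rate = 0, trajectory = FALSE,
    # qc
    loess_span = 0.5, sd_cut = 3, min_genes = 200L, max_mito_pct = 10,
    gene_min_cells = 10L,
    # features / pcs
    n_var = 2000L, pc_var_threshold = 0.01, pc_n_max = 100L,
    # clustering
    knn_k = 20L, n_pcs = 20L,
    methods = c("slm", "louvain", "walktrap", "density_peaks", "gmm"),
    consensus_height = 0.2, min_de_genes = 10L, auroc_min = 0.7,
    # ordering
    n_trees = 1000L, mst_frac = 2 / 3, mds_dim = 3L, max_nodes = 100L,
    # clones
    q4_proportion = 0.43, clone_p_rg_only = 0.05, clone_chase_days = 507L,
    clone_n_hemispheres = 11L,
    # global
    seed = 1L, out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

# derive independent per-stage seeds from the global seed so that toggling
# one stage does not perturb another stage's random stream
.stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, qc = 23L, cluster = 37L, score = 53L,
               order = 71L, clones = 97L)
  (config$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order (simulate, QC, consensus
#' clustering, scoring/gating, pseudo-ordering, clonal statistics), writes
#' stage outputs under \code{out_dir} when given, and returns a manifest
#' of the seeds, parameters and artifacts of the run. Identical config and
#' seed reproduce identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param counts optional precomputed genes x cells counts (skips the
#'   simulate stage).
#' @return list of class \code{pipeline_result}: stage outputs plus
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = pipeline_config(), counts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  manifest <- list(config = unclass(config),
                   seeds = list(), artifacts = character(0))
  out_dir <- config$out_dir
  save <- function(obj, name, writer) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- file.path(out_dir, name)
      writer(obj, p)
      manifest$artifacts <<- c(manifest$artifacts, p)
    }
  }

  truth <- NULL
  if (is.null(counts)) {
    if (!config$do_simulate)
      stop("stage dependency error: no counts and simulate disabled")
    s <- .stage_seed(config, "simulate")
    manifest$seeds$simulate <- s
    cfg <- sim_config(n_cells = config$n_cells, n_genes = config$n_genes,
                      n_clusters = config$n_clusters,
                      n_markers_per_cluster = config$n_markers_per_cluster,
                      marker_logfc = config$marker_logfc,
                      libsize_mean = config$libsize_mean,
                      lowq_fraction = config$lowq_fraction,
                      trajectory = config$trajectory, seed = s)
    sim <- if (config$trajectory) generate_trajectory_counts(cfg)
           else generate_counts(cfg)
    if (config$doublet_rate > 0)
      sim <- inject_doublets(sim$counts, sim$truth, config$doublet_rate,
                             seed = s + 1L)
    counts <- sim$counts
    truth <- sim$truth
    res$truth <- truth
    save(counts, "counts", function(o, p) write_counts(o, p))
  }

  if (config$do_qc) {
    qc <- compute_cell_qc(counts)
    thr <- qc_thresholds(loess_span = config$loess_span,
                         sd_cut = config$sd_cut,
                         min_genes = config$min_genes,
                         max_mito_pct = config$max_mito_pct,
                         gene_min_cells = config$gene_min_cells)
    lo <- loess_complexity_filter(qc, thr)
    counts <- threshold_filter(counts, qc, thr, loess_keep = lo)
    res$qc <- qc
    res$qc_keep <- lo
    save(qc, "cell_qc.tsv", function(o, p) write_tsv_table(o, p))
  }
  res$counts <- counts

  if (config$do_cluster) {
    s <- .stage_seed(config, "cluster")
    manifest$seeds$cluster <- s
    cl <- consensus_cluster(counts, k = config$knn_k,
                            n_pcs = config$n_pcs, n_var = config$n_var,
                            methods = config$methods,
                            height = config$consensus_height,
                            min_de_genes = config$min_de_genes, seed = s)
    res$clustering <- cl
    save(data.frame(cell_id = colnames(counts), label = cl$labels),
         "labels.tsv", function(o, p) write_tsv_table(o, p))
  }

  if (config$do_score) {
    s <- .stage_seed(config, "score")
    manifest$seeds$score <- s
    norm <- normalize_counts(counts)
    sc <- tryCatch(gate_populations(score_populations(norm, seed = s)),
                   error = function(e) {
                     warning("scoring skipped: ", conditionMessage(e))
                     NULL
                   })
    res$scores <- sc
    if (!is.null(sc))
      save(sc, "scores.tsv", function(o, p) write_tsv_table(o, p))
  }

  if (config$do_order) {
    if (!config$do_cluster && is.null(res$clustering))
      stop("stage dependency error: ordering requires clustering")
    s <- .stage_seed(config, "order")
    manifest$seeds$order <- s
    norm <- normalize_counts(counts)
    vg <- res$clustering$variable_genes
    dm <- diffusion_map(norm, vg, n_components = 5L)
    td <- bootstrap_mst_distances(dm, n_trees = config$n_trees,
                                  frac = config$mst_frac, seed = s)
    emb <- mds_embed(td, dim = config$mds_dim)
    pg <- fit_principal_graph(emb, max_nodes = config$max_nodes)
    pg <- prune_same_cluster_paths(pg, emb, res$clustering$labels)
    ord <- project_and_order(pg, emb, root = 1L)
    res$trajectory <- list(embedding = emb, graph = pg, order = ord)
    save(ord, "pseudo_order.tsv", function(o, p) write_tsv_table(o, p))
  }

  if (config$do_clones) {
    s <- .stage_seed(config, "clones")
    manifest$seeds$clones <- s
    clones <- generate_clone_table(
      n_hemispheres = config$clone_n_hemispheres,
      p_rg_only = config$clone_p_rg_only,
      chase_days = config$clone_chase_days, seed = s)
    res$clone_report <- compare_clone_vs_population(
      clones, config$q4_proportion, n_boot = 2000L, seed = s)
    save(clones, "clones.tsv", function(o, p) write_tsv_table(o, p))
  }

  res$manifest <- manifest
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result with stages:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  if (!is.null(x$clustering))
    cat("  clusters:", length(unique(x$clustering$labels)), "\n")
  if (!is.null(x$counts))
    cat("  counts:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  invisible(x)
}
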