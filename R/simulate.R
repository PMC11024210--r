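#' Simulation configuration for synthetic single-cell counts
#'
#' Bundles and validates every knob of the synthetic count generator. The
#' generator emulates droplet scRNA-seq of an adult neurogenic niche:
#' negative-binomial counts with log-normal library-size variation,
#' cluster-specific marker programs, an optional continuous quiescence-depth
#' axis driving opposed "deep" and "shallow" gene modules, mitochondrial
#' genes recognizable by an \code{mt-} name prefix, a low-quality cell mode
#' with shrunken libraries and elevated mitochondrial load, and injected
#' doublets.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes.
#' @param n_clusters number of planted clusters.
#' @param n_markers_per_cluster markers planted per cluster (disjoint sets).
#' @param marker_logfc natural-log fold change of a marker inside its
#'   cluster: marker means are multiplied by \code{exp(marker_logfc)}.
#' @param libsize_mean mean library size (total UMI) of a good cell.
#' @param libsize_dispersion sdlog of the log-normal library-size law.
#' @param nb_dispersion negative-binomial size parameter \eqn{\theta}
#'   (variance \eqn{\mu + \mu^2/\theta}).
#' @param mito_fraction_mean expected mitochondrial count fraction of a good
#'   cell, in \[0,1\].
#' @param lowq_fraction fraction of cells drawn from the low-quality mode
#'   (library scaled to 10\%, mitochondrial fraction inflated).
#' @param doublet_rate fraction of doublets appended by
#'   \code{\link{inject_doublets}} when run through the pipeline.
#' @param trajectory logical; plant a continuous depth axis instead of, or on
#'   top of, discrete clusters (see \code{\link{generate_trajectory_counts}}).
#' @param depth_module_size genes per depth module (deep and shallow each).
#' @param depth_logfc natural-log fold change between the two ends of the
#'   depth axis for depth-module genes.
#' @param branch logical; add a Y-branch beyond \code{branch_point}.
#' @param branch_point depth at which the two branches separate.
#' @param branch_module_size genes per branch-specific module.
#' @param lowq_mito_factor multiplier on \code{mito_fraction_mean} for
#'   low-quality cells.
#' @param seed integer seed; same seed, same output, bit for bit.
#' @return an object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_cells = 1000L, n_genes = 2000L, n_clusters = 6L,
                       n_markers_per_cluster = 30L, marker_logfc = 2,
                       libsize_mean = 2500, libsize_dispersion = 0.35,
                       nb_dispersion = 10, mito_fraction_mean = 0.03,
                       lowq_fraction = 0, doublet_rate = 0,
                       trajectory = FALSE, depth_module_size = 40L,
                       depth_logfc = log(2), branch = FALSE,
                       branch_point = 0.6, branch_module_size = 30L,
                       lowq_mito_factor = 6, seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_clusters = as.integer(n_clusters),
              n_markers_per_cluster = as.integer(n_markers_per_cluster),
              marker_logfc = marker_logfc, libsize_mean = libsize_mean,
              libsize_dispersion = libsize_dispersion,
              nb_dispersion = nb_dispersion,
              mito_fraction_mean = mito_fraction_mean,
              lowq_fraction = lowq_fraction, doublet_rate = doublet_rate,
              trajectory = isTRUE(trajectory),
              depth_module_size = as.integer(depth_module_size),
              depth_logfc = depth_logfc, branch = isTRUE(branch),
              branch_point = branch_point,
              branch_module_size = as.integer(branch_module_size),
              lowq_mito_factor = lowq_mito_factor, seed = as.integer(seed))
  num <- unlist(cfg[c("marker_logfc", "libsize_mean", "libsize_dispersion",
                      "nb_dispersion", "mito_fraction_mean", "lowq_fraction",
                      "doublet_rate", "depth_logfc", "branch_point",
                      "lowq_mito_factor")])
  if (any(!is.finite(num))) stop("non-finite parameter in sim_config")
  if (cfg$n_cells < 0L || cfg$n_genes <= 0L || cfg$n_clusters <= 0L)
    stop("n_cells must be >= 0; n_genes and n_clusters positive")
  if (cfg$n_markers_per_cluster < 0L)
    stop("n_markers_per_cluster must be non-negative")
  frac <- unlist(cfg[c("mito_fraction_mean", "lowq_fraction", "doublet_rate")])
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$doublet_rate >= 1) stop("doublet_rate must be < 1")
  if (cfg$libsize_mean <= 0 || cfg$libsize_dispersion <= 0 ||
      cfg$nb_dispersion <= 0)
    stop("libsize_mean, libsize_dispersion, nb_dispersion must be positive")
  n_marked <- cfg$n_markers_per_cluster * cfg$n_clusters
  n_mito <- ceiling(0.02 * cfg$n_genes)
  if (n_marked + n_mito > cfg$n_genes)
    stop("n_markers_per_cluster * n_clusters exceeds available genes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells x", x$n_genes, "genes,",
      x$n_clusters, "clusters,", x$n_markers_per_cluster, "markers/cluster\n")
  cat("  libsize ~ lognormal(mean", x$libsize_mean, ", sdlog",
      x$libsize_dispersion, "); NB theta", x$nb_dispersion, "\n")
  cat("  lowq", x$lowq_fraction, "| doublets", x$doublet_rate,
      "| trajectory", x$trajectory, "| seed", x$seed, "\n")
  invisible(x)
}

# Gene-level scaffolding shared by the discrete and trajectory generators:
# relative abundances, mito gene block, marker block boundaries.
.sim_gene_plan <- function(cfg) {
  n_mito <- ceiling(0.02 * cfg$n_genes)
  gene_names <- c(sprintf("mt-%d", seq_len(n_mito)),
                  sprintf("gene%d", seq_len(cfg$n_genes - n_mito)))
  # relative abundance: lognormal, heavy-tailed as in real transcriptomes
  abund <- exp(stats::rnorm(cfg$n_genes, mean = 0, sd = 1.2))
  list(n_mito = n_mito, gene_names = gene_names, abund = abund)
}

# Draw the count matrix given per-cell expected totals and per-gene rates.
# rates: genes x cells matrix of relative rates (columns need not sum to 1,
# they are normalized per cell); libsize: per-cell expected totals.
.sim_draw_counts <- function(rates, libsize, theta, gene_names) {
  n_genes <- nrow(rates); n_cells <- ncol(rates)
  mu <- sweep(rates, 2, colSums(rates), "/")
  mu <- sweep(mu, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(n_genes * n_cells, size = theta,
                                  mu = as.numeric(mu)),
                   nrow = n_genes, ncol = n_cells)
  rownames(counts) <- gene_names
  colnames(counts) <- sprintf("cell%d", seq_len(n_cells))
  methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
}

.empty_truth <- function() {
  list(cell = character(0), cluster = integer(0), depth = numeric(0),
       is_doublet = logical(0), is_lowq = logical(0),
       marker_sets = list(), depth_genes = character(0))
}

#' Generate synthetic counts with planted clusters
#'
#' Draws a sparse gene-by-cell matrix of negative-binomial counts with
#' log-normal library sizes, planted marker programs per cluster, an
#' \code{mt-} gene block carrying the mitochondrial fraction, and an optional
#' low-quality subpopulation whose libraries are scaled to 10\% with an
#' inflated mitochondrial share (yielding the bimodal detected-gene histogram
#' that motivates the QC complexity filter).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a list with \code{counts} (dgCMatrix, genes x cells) and
#'   \code{truth} (per-cell \code{cluster}, \code{is_lowq},
#'   \code{is_doublet}, \code{depth}; plus \code{marker_sets}, a list of
#'   marker gene names per cluster).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cells == 0L) {
    counts <- Matrix::Matrix(0L, nrow = config$n_genes, ncol = 0,
                             sparse = TRUE)
    rownames(counts) <- .sim_gene_plan(config)$gene_names
    return(list(counts = counts, truth = .empty_truth()))
  }
  set.seed(config$seed)
  plan <- .sim_gene_plan(config)
  n <- config$n_cells

  cluster <- sample.int(config$n_clusters, n, replace = TRUE)
  is_lowq <- stats::runif(n) < config$lowq_fraction

  meanlog <- log(config$libsize_mean) - config$libsize_dispersion^2 / 2
  libsize <- exp(stats::rnorm(n, meanlog, config$libsize_dispersion))
  libsize[is_lowq] <- libsize[is_lowq] * 0.1

  # marker blocks start right after the mito block
  marker_sets <- vector("list", config$n_clusters)
  nm <- config$n_markers_per_cluster
  for (k in seq_len(config$n_clusters)) {
    idx <- plan$n_mito + (k - 1L) * nm + seq_len(nm)
    marker_sets[[k]] <- plan$gene_names[idx]
  }
  names(marker_sets) <- sprintf("cluster%d", seq_len(config$n_clusters))

  rates <- matrix(plan$abund, nrow = config$n_genes, ncol = n)
  if (nm > 0L) {
    fc <- exp(config$marker_logfc)
    for (k in seq_len(config$n_clusters)) {
      idx <- match(marker_sets[[k]], plan$gene_names)
      rates[idx, cluster == k] <- rates[idx, cluster == k] * fc
    }
  }

  # impose mito share: mito block carries fraction f of the cell's rate mass
  f <- ifelse(is_lowq,
              pmin(config$mito_fraction_mean * config$lowq_mito_factor, 0.6),
              config$mito_fraction_mean)
  mito_idx <- seq_len(plan$n_mito)
  mito_mass <- colSums(rates[mito_idx, , drop = FALSE])
  rest_mass <- colSums(rates) - mito_mass
  rates[mito_idx, ] <- sweep(rates[mito_idx, , drop = FALSE], 2,
                             f * rest_mass / ((1 - f) * mito_mass), "*")

  counts <- .sim_draw_counts(rates, libsize, config$nb_dispersion,
                             plan$gene_names)
  truth <- list(cell = colnames(counts), cluster = cluster,
                depth = rep(NA_real_, n), is_doublet = rep(FALSE, n),
                is_lowq = is_lowq, marker_sets = marker_sets,
                depth_genes = character(0))
  list(counts = counts, truth = truth)
}

#' Append artificial doublets to a count matrix
#'
#' Each doublet is the gene-wise sum of two distinct randomly chosen singlet
#' columns, so column sums are conserved exactly; doublets are flagged in the
#' returned truth. This provides ground truth for the mock-doublet detector.
#'
#' @param counts genes x cells count matrix.
#' @param truth truth list from a generator (or NULL for a bare matrix).
#' @param rate doublets to append, as a fraction of the existing cells;
#'   must satisfy \code{0 <= rate < 1}.
#' @param seed integer seed.
#' @return list with augmented \code{counts} and \code{truth}; the truth
#'   records parent indices in \code{doublet_parents}.
#' @export
inject_doublets <- function(counts, truth = NULL, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("rate must lie in [0, 1)")
  n <- ncol(counts)
  n_doub <- round(rate * n)
  if (is.null(truth)) {
    truth <- list(cell = colnames(counts), cluster = rep(NA_integer_, n),
                  depth = rep(NA_real_, n), is_doublet = rep(FALSE, n),
                  is_lowq = rep(FALSE, n), marker_sets = list(),
                  depth_genes = character(0))
  }
  if (n_doub == 0L) return(list(counts = counts, truth = truth))
  set.seed(seed)
  parents <- t(vapply(seq_len(n_doub), function(i) sample.int(n, 2L),
                      integer(2)))
  doub <- counts[, parents[, 1L], drop = FALSE] +
    counts[, parents[, 2L], drop = FALSE]
  colnames(doub) <- sprintf("doublet%d", seq_len(n_doub))
  out <- methods::cbind2(counts, doub)
  truth$cell <- c(truth$cell, colnames(doub))
  truth$cluster <- c(truth$cluster, rep(NA_integer_, n_doub))
  truth$depth <- c(truth$depth, rep(NA_real_, n_doub))
  truth$is_doublet <- c(truth$is_doublet, rep(TRUE, n_doub))
  truth$is_lowq <- c(truth$is_lowq, rep(FALSE, n_doub))
  truth$doublet_parents <- parents
  list(counts = out, truth = truth)
}

#' Generate counts along a planted quiescence-depth axis
#'
#' Cells receive a latent depth drawn uniformly on \[0,1\]. A "deep" gene
#' module rises multiplicatively with depth and a "shallow" module with
#' \eqn{1 - depth}, emulating the graded transcriptional axis from deep
#' dormancy to activation readiness. Optionally a Y-branch adds two
#' branch-specific modules beyond a branch point.
#'
#' @param config a \code{\link{sim_config}} with \code{trajectory = TRUE}.
#' @return list with \code{counts} and \code{truth}; the truth carries
#'   per-cell \code{depth}, \code{branch} (0 before the branch point, 1/2
#'   after when branching is enabled) and the signed \code{depth_genes}
#'   (names prefixed \code{+}/\code{-} for deep/shallow association).
#' @export
generate_trajectory_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$trajectory) stop("trajectory not enabled in config")
  if (config$depth_module_size <= 0L)
    stop("depth_module_size must be positive when trajectory is enabled")
  set.seed(config$seed)
  plan <- .sim_gene_plan(config)
  n <- config$n_cells
  m <- config$depth_module_size
  need <- 2L * m + if (config$branch) 2L * config$branch_module_size else 0L
  if (plan$n_mito + need > config$n_genes)
    stop("not enough genes for the requested depth/branch modules")

  depth <- stats::runif(n)
  branch <- rep(0L, n)
  if (config$branch)
    branch[depth > config$branch_point] <-
      sample(c(1L, 2L), sum(depth > config$branch_point), replace = TRUE)

  meanlog <- log(config$libsize_mean) - config$libsize_dispersion^2 / 2
  libsize <- exp(stats::rnorm(n, meanlog, config$libsize_dispersion))

  deep_idx <- plan$n_mito + seq_len(m)
  shallow_idx <- plan$n_mito + m + seq_len(m)
  rates <- matrix(plan$abund, nrow = config$n_genes, ncol = n)
  fold <- exp(config$depth_logfc)
  mult_deep <- 1 + (fold - 1) * depth        # mean rises linearly with depth
  mult_shal <- 1 + (fold - 1) * (1 - depth)
  rates[deep_idx, ] <- sweep(rates[deep_idx, , drop = FALSE], 2, mult_deep, "*")
  rates[shallow_idx, ] <- sweep(rates[shallow_idx, , drop = FALSE], 2, mult_shal, "*")

  branch_sets <- list()
  if (config$branch) {
    bm <- config$branch_module_size
    for (b in 1:2) {
      idx <- plan$n_mito + 2L * m + (b - 1L) * bm + seq_len(bm)
      excess <- pmax(depth - config$branch_point, 0) *
        (branch == b) / (1 - config$branch_point)
      mult <- 1 + (fold - 1) * 2 * excess
      rates[idx, ] <- sweep(rates[idx, , drop = FALSE], 2, mult, "*")
      branch_sets[[b]] <- plan$gene_names[idx]
    }
  }

  counts <- .sim_draw_counts(rates, libsize, config$nb_dispersion,
                             plan$gene_names)
  truth <- list(cell = colnames(counts), cluster = rep(1L, n), depth = depth,
                branch = branch, is_doublet = rep(FALSE, n),
                is_lowq = rep(FALSE, n), marker_sets = list(),
                depth_genes = c(paste0("+", plan$gene_names[deep_idx]),
                                paste0("-", plan$gene_names[shallow_idx])),
                branch_sets = branch_sets)
  list(counts = counts, truth = truth)
}

#' Generate a synthetic clone table
#'
#' Emulates sparse-induction lineage tracing read out per hemisphere: each
#' hemisphere at each chase time contains a small number of clones, and each
#' clone is independently radial-glia-only with the timepoint's probability.
#'
#' @param n_hemispheres hemispheres per chase timepoint.
#' @param clones_per_hemisphere integer vector of possible clone counts per
#'   hemisphere (sampled uniformly), e.g. \code{4:11}.
#' @param p_rg_only probability that a clone contains only radial glia;
#'   scalar or one value per element of \code{chase_days}.
#' @param chase_days integer vector of chase durations in days.
#' @param seed integer seed.
#' @return data.frame with columns \code{clone_id}, \code{hemisphere_id},
#'   \code{chase_days}, \code{composition} (\code{"RG_only"}/\code{"mixed"}).
#' @export
generate_clone_table <- function(n_hemispheres, clones_per_hemisphere = 4:11,
                                 p_rg_only, chase_days, seed = 1L) {
  if (length(chase_days) == 0L) stop("chase_days must be nonempty")
  if (any(p_rg_only < 0 | p_rg_only > 1)) stop("p_rg_only must be in [0, 1]")
  p <- rep_len(p_rg_only, length(chase_days))
  set.seed(seed)
  rows <- list()
  clone_counter <- 0L
  for (t in seq_along(chase_days)) {
    for (h in seq_len(n_hemispheres)) {
      nc <- if (length(clones_per_hemisphere) == 1L) clones_per_hemisphere
            else sample(clones_per_hemisphere, 1L)
      comp <- ifelse(stats::runif(nc) < p[t], "RG_only", "mixed")
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = sprintf("clone%d", clone_counter + seq_len(nc)),
        hemisphere_id = sprintf("d%d_h%d", chase_days[t], h),
        chase_days = chase_days[t], composition = comp,
        stringsAsFactors = FALSE)
      clone_counter <- clone_counter + nc
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic two-species ortholog table
#'
#' Two species ("zf" and "mm") share \code{n_groups} ortholog groups. A
#' fraction of groups carries two zf genes for one mm gene (teleost-style
#' duplicates after the extra whole-genome duplication); another fraction is
#' missing from one species. Counts are deterministic
#' (\code{round(frac * n_groups)}).
#'
#' @param n_groups number of ortholog groups.
#' @param frac_one2many fraction of groups with two zf paralogs.
#' @param frac_missing fraction of groups absent from one species (split
#'   evenly between the two).
#' @param seed integer seed (drives which species loses a missing group).
#' @return data.frame with columns \code{species}, \code{gene_id},
#'   \code{group_id}.
#' @export
generate_ortholog_table <- function(n_groups, frac_one2many = 0,
                                    frac_missing = 0, seed = 1L) {
  if (frac_one2many < 0 || frac_missing < 0 ||
      frac_one2many + frac_missing > 1)
    stop("fractions must be non-negative and sum to at most 1")
  set.seed(seed)
  n_multi <- round(frac_one2many * n_groups)
  n_miss <- round(frac_missing * n_groups)
  group_id <- sprintf("OG%04d", seq_len(n_groups))
  kind <- rep("one2one", n_groups)
  if (n_multi > 0L) kind[seq_len(n_multi)] <- "one2many"
  if (n_miss > 0L)
    kind[n_multi + seq_len(n_miss)] <-
      sample(c("miss_zf", "miss_mm"), n_miss, replace = TRUE)
  rows <- list()
  for (g in seq_len(n_groups)) {
    zf <- if (kind[g] == "one2many")
      sprintf("zf_%s_%s", group_id[g], c("a", "b"))
    else if (kind[g] != "miss_zf") sprintf("zf_%s", group_id[g])
    else character(0)
    mm <- if (kind[g] != "miss_mm") sprintf("mm_%s", group_id[g])
          else character(0)
    rows[[g]] <- data.frame(
      species = c(rep("zf", length(zf)), rep("mm", length(mm))),
      gene_id = c(zf, mm), group_id = group_id[g], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
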