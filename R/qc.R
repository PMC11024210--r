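#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the total molecule count (nUMI), the number of
#' detected genes (nGene, counts > 0) and the percentage of the transcriptome
#' mapping to mitochondrial genes, identified by gene-name prefix.
#'
#' @param counts genes x cells matrix of non-negative integer counts with
#'   gene names as rownames.
#' @param mito_pattern regex identifying mitochondrial genes by name
#'   (default \code{"^mt-"}, case-insensitive).
#' @return data.frame with columns \code{cell_id}, \code{nUMI},
#'   \code{nGene}, \code{percent.mito} (0 for empty cells).
#' @export
compute_cell_qc <- function(counts, mito_pattern = "^mt-") {
  if (nrow(counts) == 0L) stop("count matrix has no genes")
  nUMI <- Matrix::colSums(counts)
  nGene <- Matrix::colSums(counts > 0)
  mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  mito_counts <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  pct <- ifelse(nUMI > 0, 100 * mito_counts / nUMI, 0)
  data.frame(cell_id = colnames(counts), nUMI = as.numeric(nUMI),
             nGene = as.integer(nGene), percent.mito = as.numeric(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' QC thresholds
#'
#' Container for the cell/gene filtering thresholds. Defaults are the
#' standard choices for this kind of dataset: loess span 0.5 with a 3-SD
#' residual cut on the nGene~nUMI relationship, minimum 200 detected genes,
#' maximum 10\% mitochondrial counts, and genes kept when expressed in at
#' least 10 cells.
#'
#' @param loess_span span of the complexity loess.
#' @param sd_cut residual cut in standard deviations (two-sided).
#' @param min_genes cells with \code{nGene < min_genes} are removed (strict).
#' @param max_mito_pct cells with \code{percent.mito > max_mito_pct} are
#'   removed (strict).
#' @param gene_min_cells genes expressed in fewer than this many surviving
#'   cells are removed.
#' @return a list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(loess_span = 0.5, sd_cut = 3, min_genes = 200L,
                          max_mito_pct = 10, gene_min_cells = 10L) {
  stopifnot(loess_span > 0, sd_cut > 0, min_genes >= 0, max_mito_pct >= 0,
            gene_min_cells >= 0)
  structure(list(loess_span = loess_span, sd_cut = sd_cut,
                 min_genes = as.integer(min_genes),
                 max_mito_pct = max_mito_pct,
                 gene_min_cells = as.integer(gene_min_cells)),
            class = "qc_thresholds")
}

#' Library-complexity filter by loess regression of nGene on nUMI
#'
#' Detected genes are expected to grow with total molecules; cells far below
#' the trend have low library complexity (degraded or empty droplets) and
#' cells far above it suggest excessive complexity (likely doublets). A
#' loess curve (gaussian family, degree 2, tricube weights) of nGene on nUMI
#' is fit and cells whose residual exceeds \code{sd_cut} standard deviations
#' of the residuals, on either side, are flagged.
#'
#' @param qc data.frame from \code{\link{compute_cell_qc}}.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param two_sided flag both tails (default) or only low-complexity cells.
#' @return data.frame with \code{cell_id}, \code{residual}, \code{keep}.
#' @export
loess_complexity_filter <- function(qc, thresholds = qc_thresholds(),
                                    two_sided = TRUE) {
  if (nrow(qc) < 10L) stop("need at least 10 cells for the loess filter")
  if (stats::sd(qc$nUMI) == 0)
    stop("degenerate input: nUMI is constant across cells")
  fit <- stats::loess(nGene ~ nUMI, data = qc, span = thresholds$loess_span,
                      degree = 2, family = "gaussian")
  res <- stats::residuals(fit)
  s <- stats::sd(res)
  flag <- if (s == 0) rep(FALSE, nrow(qc))
          else if (two_sided) abs(res) > thresholds$sd_cut * s
          else res < -thresholds$sd_cut * s
  data.frame(cell_id = qc$cell_id, residual = as.numeric(res),
             keep = !flag, stringsAsFactors = FALSE)
}

#' Threshold-based cell and gene filtering
#'
#' Removes cells with too few detected genes (strict \code{<}), too much
#' mitochondrial signal (strict \code{>}) or a loess-complexity flag; then
#' removes genes expressed in fewer than \code{gene_min_cells} of the
#' surviving cells. Cell filtering happens before gene filtering.
#'
#' @param counts genes x cells count matrix.
#' @param qc data.frame from \code{\link{compute_cell_qc}} matching
#'   \code{counts} column order.
#' @param thresholds a \code{\link{qc_thresholds}}.
#' @param loess_keep optional logical vector (or the data.frame returned by
#'   \code{\link{loess_complexity_filter}}) of cells to keep on complexity.
#' @return the filtered count matrix, with attributes \code{cells_removed}
#'   and \code{genes_removed}.
#' @export
threshold_filter <- function(counts, qc, thresholds = qc_thresholds(),
                             loess_keep = NULL) {
  stopifnot(nrow(qc) == ncol(counts))
  keep <- qc$nGene >= thresholds$min_genes &
    qc$percent.mito <= thresholds$max_mito_pct
  if (!is.null(loess_keep)) {
    if (is.data.frame(loess_keep)) loess_keep <- loess_keep$keep
    stopifnot(length(loess_keep) == ncol(counts))
    keep <- keep & loess_keep
  }
  if (!any(keep)) stop("all cells removed by QC thresholds")
  out <- counts[, keep, drop = FALSE]
  gkeep <- Matrix::rowSums(out > 0) >= thresholds$gene_min_cells
  res <- out[gkeep, , drop = FALSE]
  attr(res, "cells_removed") <- colnames(counts)[!keep]
  attr(res, "genes_removed") <- rownames(counts)[!gkeep]
  res
}

#' Library-size normalization
#'
#' Counts-per-10k followed by log1p; the standard normalization used by all
#' downstream stages (scoring, differential expression, trajectories).
#'
#' @param counts genes x cells count matrix.
#' @param scale_factor target library size (default 1e4).
#' @return dgCMatrix of log-normalized expression.
#' @export
normalize_counts <- function(counts, scale_factor = 1e4) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / libs)
  norm@x <- log1p(norm@x)
  colnames(norm) <- colnames(counts)
  methods::as(norm, "CsparseMatrix")
}

# sparse per-gene means and variances without densifying
.row_mean_var <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowSums(m) / n
  ex2 <- Matrix::rowSums(m^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = as.numeric(mu), var = pmax(as.numeric(v), 0))
}

#' Variance-stabilized selection of highly variable genes
#'
#' Selects genes exhibiting high variability given their level of
#' expression, without a fixed global threshold: a loess curve of
#' log10(variance) on log10(mean) predicts each gene's expected standard
#' deviation, counts are standardized against it with values clipped at
#' \eqn{\sqrt{n}}, and genes are ranked by the variance of the clipped
#' standardized counts.
#'
#' @param counts genes x cells raw count matrix.
#' @param n_top number of genes to return (default 2000; 0 gives an empty
#'   list).
#' @param loess_span span for the mean-variance trend fit.
#' @return character vector of gene names, with the full ranking table in
#'   attribute \code{ranking} (gene, mean, variance, standardized variance).
#' @export
select_variable_genes <- function(counts, n_top = 2000L, loess_span = 0.3) {
  if (ncol(counts) < 2L) stop("need at least 2 cells")
  mv <- .row_mean_var(counts)
  ok <- mv$mean > 0 & mv$var > 0
  if (!any(ok)) {
    out <- character(0)
    attr(out, "ranking") <- data.frame(gene = character(0))
    return(out)
  }
  fit <- stats::loess(log10(var) ~ log10(mean),
                      data = data.frame(mean = mv$mean[ok], var = mv$var[ok]),
                      span = loess_span, degree = 2)
  exp_sd <- sqrt(10^stats::fitted(fit))
  n <- ncol(counts)
  clip <- sqrt(n)
  std_var <- rep(0, nrow(counts))
  idx_ok <- which(ok)
  z <- as.matrix(counts[idx_ok, , drop = FALSE])
  z <- (z - mv$mean[idx_ok]) / exp_sd
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  std_var[idx_ok] <- apply(z, 1, stats::var)
  ord <- order(std_var, decreasing = TRUE)
  rk <- data.frame(gene = rownames(counts)[ord], mean = mv$mean[ord],
                   variance = mv$var[ord], std_variance = std_var[ord],
                   stringsAsFactors = FALSE)
  top <- utils::head(rk$gene[rk$std_variance > 0], n_top)
  attr(top, "ranking") <- rk
  top
}

#' Scale and run PCA on a gene subset
#'
#' Rows (genes) are centered and unit-scaled (scale capped at 10 standard
#' units as usual) and PCA is run with cells as observations.
#'
#' @param normalized genes x cells normalized matrix.
#' @param genes gene subset (default all rows).
#' @param n_pcs components to retain.
#' @return list with \code{scores} (cells x PCs), \code{loadings},
#'   \code{sdev}, \code{var_share} (share of total variance among retained
#'   PCs).
#' @export
run_pca <- function(normalized, genes = rownames(normalized), n_pcs = 50L) {
  x <- as.matrix(normalized[intersect(genes, rownames(normalized)), ,
                            drop = FALSE])
  x <- t(scale(t(x)))
  x[!is.finite(x)] <- 0
  x[x > 10] <- 10
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x) - 1L)
  p <- stats::prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_pcs)
  tot <- sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, sdev = p$sdev[seq_len(n_pcs)],
       var_share = p$sdev[seq_len(n_pcs)]^2 / tot)
}

#' Select significant principal components
#'
#' A component is retained when it explains more than \code{var_threshold}
#' of the variance across the first \code{n_max} components AND is flagged
#' significant by a JackStraw-style permutation test: a small fraction of
#' genes is repeatedly permuted across cells and re-projected onto the
#' component, giving a null distribution of loadings; each real gene gets an
#' empirical p-value, and the component's p-value is a binomial test of
#' whether more genes than expected beat the nominal level.
#'
#' @param normalized genes x cells normalized matrix.
#' @param variable_genes genes to use.
#' @param n_max number of leading components examined (default 100).
#' @param var_threshold minimum variance share (default 0.01).
#' @param jackstraw_reps permutation replicates (default 100).
#' @param jackstraw_frac fraction of genes permuted per replicate.
#' @param alpha significance level for both the per-gene tail count and the
#'   component-level binomial test.
#' @param seed integer seed for the permutations.
#' @return integer: number of significant leading components; attributes
#'   \code{var_share} and \code{pc_pvalues}.
#' @export
select_pcs <- function(normalized, variable_genes, n_max = 100L,
                       var_threshold = 0.01, jackstraw_reps = 100L,
                       jackstraw_frac = 0.01, alpha = 0.05, seed = 1L) {
  if (length(variable_genes) == 0L) stop("variable_genes is empty")
  x <- as.matrix(normalized[intersect(variable_genes, rownames(normalized)), ,
                            drop = FALSE])
  x <- t(scale(t(x)))
  x[!is.finite(x)] <- 0
  x[x > 10] <- 10
  n_max <- min(n_max, nrow(x) - 1L, ncol(x) - 1L)
  p <- stats::prcomp(t(x), center = FALSE, rank. = n_max)
  var_share <- p$sdev[seq_len(n_max)]^2 / sum(p$sdev[seq_len(n_max)]^2)

  set.seed(seed)
  n_genes <- nrow(x)
  n_perm_genes <- max(1L, round(jackstraw_frac * n_genes))
  # JackStraw: permute a small random fraction of genes across cells,
  # recompute the PCA with them included, and collect the permuted genes'
  # loadings as the null distribution per component
  null_load <- matrix(NA_real_, jackstraw_reps * n_perm_genes, n_max)
  for (r in seq_len(jackstraw_reps)) {
    gi <- sample.int(n_genes, n_perm_genes)
    xp <- x
    xp[gi, ] <- t(apply(xp[gi, , drop = FALSE], 1, sample))
    pr <- stats::prcomp(t(xp), center = FALSE, rank. = n_max)
    null_load[(r - 1L) * n_perm_genes + seq_len(n_perm_genes), ] <-
      pr$rotation[gi, seq_len(n_max)]
  }
  obs_load <- p$rotation[, seq_len(n_max), drop = FALSE]   # genes x PC
  pc_p <- vapply(seq_len(n_max), function(j) {
    nl <- abs(null_load[, j])
    gene_p <- (1 + vapply(abs(obs_load[, j]),
                          function(v) sum(nl >= v), numeric(1))) /
      (1 + length(nl))
    k <- sum(gene_p < alpha)
    stats::pbinom(k - 1L, n_genes, alpha, lower.tail = FALSE)
  }, numeric(1))

  sig <- var_share > var_threshold & pc_p < alpha
  # keep the leading run of significant components
  n_sig <- if (!sig[1L]) 0L else which.min(c(sig, FALSE)) - 1L
  out <- as.integer(n_sig)
  attr(out, "var_share") <- var_share
  attr(out, "pc_pvalues") <- pc_p
  out
}
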