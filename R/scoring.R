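#' Built-in gene sets for population scoring
#'
#' The glial set (GFAP, GLUL, GJA1, FABP7) marks astroglia across species;
#' the neuroblast set (NEUROD1/2/4/6, STMN1, DPYSL3, GAP43, BHLHE22, TUBB5)
#' marks committed neuronal precursors; the ribosomal set is defined by a
#' name pattern over ribosomal protein genes (default \code{^rp[sl]},
#' case-insensitive), since stem cells upregulate ribosomal protein genes on
#' their way to activation.
#'
#' @param which one of \code{"glial"}, \code{"neuroblast"},
#'   \code{"ribosomal"}.
#' @param gene_names gene universe; required for the ribosomal set, used to
#'   case-insensitively match the fixed sets otherwise.
#' @param ribo_pattern regex for ribosomal protein gene names.
#' @return character vector of gene names present in \code{gene_names}
#'   (or the canonical symbols when no universe is given).
#' @export
builtin_gene_set <- function(which = c("glial", "neuroblast", "ribosomal"),
                             gene_names = NULL, ribo_pattern = "^rp[sl]") {
  which <- match.arg(which)
  canon <- switch(which,
    glial = c("GFAP", "GLUL", "GJA1", "FABP7"),
    neuroblast = c("NEUROD1", "NEUROD2", "NEUROD4", "NEUROD6", "STMN1",
                   "DPYSL3", "GAP43", "BHLHE22", "TUBB5"),
    ribosomal = NULL)
  if (which == "ribosomal") {
    if (is.null(gene_names)) stop("ribosomal set needs gene_names")
    return(gene_names[grepl(ribo_pattern, gene_names, ignore.case = TRUE)])
  }
  if (is.null(gene_names)) return(canon)
  gene_names[toupper(gene_names) %in% canon]
}

#' Background-matched gene-set score per cell
#'
#' Scores each cell for the relative expression of a gene set against
#' expression-matched background genes: all genes are binned by average
#' expression (default 25 bins), each set gene draws \code{n_background}
#' control genes from its own bin, and the score is the mean expression of
#' the set minus the mean expression of the pooled controls. A set that is
#' uniformly highly expressed therefore scores near zero; only expression
#' that exceeds what the set's average level predicts yields a high score.
#'
#' @param normalized genes x cells normalized expression.
#' @param gene_set character vector of gene names.
#' @param n_bins expression bins (default 25).
#' @param n_background control genes drawn per set gene (default 100, with
#'   replacement when a bin is small).
#' @param seed integer seed for the control draws.
#' @return numeric per-cell score, named by cell.
#' @export
module_score <- function(normalized, gene_set, n_bins = 25L,
                         n_background = 100L, seed = 1L) {
  present <- intersect(gene_set, rownames(normalized))
  if (length(present) == 0L)
    stop("gene set entirely absent from the matrix: ",
         paste(utils::head(gene_set, 5), collapse = ", "))
  set.seed(seed)
  avg <- Matrix::rowMeans(normalized)
  # bins by average expression rank, equal occupancy
  bins <- cut(rank(avg, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- rownames(normalized)
  pools <- lapply(present, function(g) {
    pool <- names(bins)[bins == bins[g]]
    # a bin smaller than the requested draw is used in full, so the
    # controls of an all-genes set are exactly the genes themselves
    if (length(pool) <= n_background) pool else sample(pool, n_background)
  })
  # control signal is averaged within each gene's pool first, then across
  # set genes, so each set gene is matched against its own background
  ctrl_mean <- Reduce(`+`, lapply(pools, function(p)
    Matrix::colMeans(normalized[p, , drop = FALSE]))) / length(pools)
  set_mean <- Matrix::colMeans(normalized[present, , drop = FALSE])
  out <- as.numeric(set_mean - ctrl_mean)
  names(out) <- colnames(normalized)
  out
}

#' Score cells for the three built-in programs
#'
#' @param normalized genes x cells normalized expression.
#' @param seed seed for background sampling.
#' @param ribo_pattern regex for ribosomal protein gene names.
#' @return data.frame: cell_id, glial_score, ribo_score, nb_score.
#' @export
score_populations <- function(normalized, seed = 1L,
                              ribo_pattern = "^rp[sl]") {
  gn <- rownames(normalized)
  data.frame(
    cell_id = colnames(normalized),
    glial_score = module_score(normalized,
                               builtin_gene_set("glial", gn), seed = seed),
    ribo_score = module_score(normalized,
                              builtin_gene_set("ribosomal", gn,
                                               ribo_pattern = ribo_pattern),
                              seed = seed + 1L),
    nb_score = module_score(normalized,
                            builtin_gene_set("neuroblast", gn),
                            seed = seed + 2L),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Gate cells into qRG / paRG / neuroblast populations
#'
#' Quantile-based gating on the three scores: quiescent radial glia (qRG)
#' have a high glial score with low ribosomal and neuroblast scores;
#' pre-activated RG (paRG) add a high ribosomal score; neuroblasts (NB)
#' have low glial, high ribosomal and high neuroblast scores. Everything
#' else, including an optional excluded set of proliferating cells, is
#' \code{"other"}.
#'
#' @param scores data.frame from \code{\link{score_populations}}.
#' @param quantile_hi,quantile_lo quantiles defining "high" and "low"
#'   (defaults 0.7 / 0.3).
#' @param exclude optional cell ids (e.g. proliferating cells) forced to
#'   \code{"other"}.
#' @return the scores data.frame with a \code{population} column.
#' @export
gate_populations <- function(scores, quantile_hi = 0.7, quantile_lo = 0.3,
                             exclude = NULL) {
  for (col in c("glial_score", "ribo_score", "nb_score")) {
    if (stats::sd(scores[[col]]) == 0)
      stop("degenerate score distribution in ", col)
  }
  qs <- function(v) stats::quantile(v, c(quantile_lo, quantile_hi))
  g <- qs(scores$glial_score); r <- qs(scores$ribo_score)
  b <- qs(scores$nb_score)
  pop <- rep("other", nrow(scores))
  pop[scores$glial_score > g[2] & scores$ribo_score < r[1] &
        scores$nb_score < b[1]] <- "qRG"
  pop[scores$glial_score > g[2] & scores$ribo_score > r[2] &
        scores$nb_score < b[1]] <- "paRG"
  pop[scores$glial_score < g[1] & scores$ribo_score > r[2] &
        scores$nb_score > b[2]] <- "NB"
  if (!is.null(exclude)) pop[scores$cell_id %in% exclude] <- "other"
  scores$population <- pop
  scores
}

#' Signed per-gene AUROC for a target cell set
#'
#' Uses each gene as a one-dimensional classifier for membership in the
#' target set and reports the signed area under the ROC curve,
#' \eqn{2 \cdot AUC - 1}: a value bounded between -1 and 1 whose sign says
#' whether higher expression of the gene favors the target (+) or its
#' complement (-). Ranks use mid-ties.
#'
#' @param normalized genes x cells expression (any monotone scale).
#' @param target_cells logical vector over cells, or cell ids.
#' @return named numeric vector in \[-1, 1\], one value per gene; the raw
#'   AUC is in attribute \code{auc}.
#' @export
gene_signed_auroc <- function(normalized, target_cells) {
  if (!is.logical(target_cells))
    target_cells <- colnames(normalized) %in% target_cells
  n1 <- sum(target_cells); n2 <- sum(!target_cells)
  if (n1 == 0L || n2 == 0L)
    stop("target and complement must both be nonempty")
  x <- as.matrix(normalized)
  auc <- apply(x, 1, function(v) {
    r <- rank(v, ties.method = "average")
    (sum(r[target_cells]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  out <- 2 * auc - 1
  attr(out, "auc") <- auc
  out
}

# ES of one set given the decreasing-sorted weights and hit positions.
# Weighted Kolmogorov-Smirnov running sum: hits climb by |stat|^w / NR,
# misses fall by 1/(N - Nh); extremes occur at hit boundaries only.
.gsea_es <- function(abs_stat_sorted, pos, n) {
  pos <- sort(pos)
  nh <- length(pos)
  w <- abs_stat_sorted[pos]
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, nh); nr <- nh }   # degenerate all-zero stats
  hit_cum <- cumsum(w) / nr
  miss <- (pos - seq_len(nh)) / (n - nh)       # miss mass before each hit
  after <- hit_cum - miss                      # running sum just after hit
  before <- c(0, hit_cum[-nh]) - miss          # and just before it
  # between hits the sum only decreases and it ends at exactly 0, so the
  # extremes of the whole walk are among these boundary values and 0
  top <- max(after)
  bottom <- min(c(0, before))
  if (top >= -bottom) top else bottom
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment on a ranked gene
#' statistic (weight = |statistic|), with a gene-label permutation null:
#' for each permutation the set is reassigned to random positions of the
#' ranking. NES divides ES by the mean absolute null ES of the same sign;
#' p-values use the same-signed null tail and are BH-corrected across sets.
#'
#' @param ranked named numeric vector of per-gene statistics (e.g. signed
#'   AUROC from \code{\link{gene_signed_auroc}}); no missing values.
#' @param gene_sets named list of character vectors.
#' @param n_perm permutations (default 1000).
#' @param min_size sets smaller than this after intersection are skipped
#'   with a notice (default 5).
#' @param seed integer seed.
#' @return data.frame: set, size, ES, NES, p, q.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000L, min_size = 5L,
                           seed = 1L) {
  if (any(is.na(ranked))) stop("ranking contains missing values")
  set.seed(seed)
  ord <- order(ranked, decreasing = TRUE)
  stat_sorted <- ranked[ord]
  abs_sorted <- abs(stat_sorted)
  genes_sorted <- names(stat_sorted)
  n <- length(ranked)
  rows <- list()
  for (si in seq_along(gene_sets)) {
    set_name <- names(gene_sets)[si]
    pos <- which(genes_sorted %in% gene_sets[[si]])
    nh <- length(pos)
    if (nh < min_size || nh >= n) {
      message("gene set '", set_name, "' skipped (size ", nh, ")")
      next
    }
    es <- .gsea_es(abs_sorted, pos, n)
    null_es <- vapply(seq_len(n_perm), function(p)
      .gsea_es(abs_sorted, sample.int(n, nh), n), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      set = set_name, size = nh, ES = es, NES = nes, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
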