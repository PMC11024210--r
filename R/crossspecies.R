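#' Collapse a count matrix onto ortholog groups
#'
#' Renames genes into a shared ortholog-group space: all paralogs of a group
#' within the species are summed per cell (teleost one-to-many orthology is
#' thereby preserved instead of discarded), and groups absent from the
#' species are dropped. Total counts are conserved up to exactly the genes
#' without a group.
#'
#' @param counts genes x cells count matrix for one species.
#' @param ortholog_table data.frame with columns \code{species},
#'   \code{gene_id}, \code{group_id}.
#' @param species species tag to select from the table.
#' @return groups x cells matrix; attribute \code{audit} is a data.frame of
#'   every gene-to-group assignment actually used (with a
#'   \code{n_paralogs} column flagging many-to-one collapses), attribute
#'   \code{dropped_genes} lists matrix genes without a group.
#' @export
collapse_to_groups <- function(counts, ortholog_table, species) {
  tab <- ortholog_table[ortholog_table$species == species, , drop = FALSE]
  if (nrow(tab) == 0L) stop("species '", species, "' not in ortholog table")
  if (anyDuplicated(tab$gene_id))
    stop("duplicated (species, gene_id) in ortholog table")
  tab <- tab[tab$gene_id %in% rownames(counts), , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no overlap between matrix genes and ortholog table")
  groups <- sort(unique(tab$group_id))
  gi <- match(tab$gene_id, rownames(counts))
  gr <- match(tab$group_id, groups)
  # indicator matrix: groups x genes-present
  ind <- Matrix::sparseMatrix(i = gr, j = seq_along(gi), x = 1,
                              dims = c(length(groups), length(gi)))
  out <- ind %*% counts[gi, , drop = FALSE]
  rownames(out) <- groups
  colnames(out) <- colnames(counts)
  n_para <- table(tab$group_id)
  audit <- data.frame(gene_id = tab$gene_id, group_id = tab$group_id,
                      n_paralogs = as.integer(n_para[tab$group_id]),
                      stringsAsFactors = FALSE)
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "audit") <- audit
  attr(out, "dropped_genes") <- setdiff(rownames(counts), tab$gene_id)
  out
}

# Spearman-correlation voting network over the combined cells, restricted
# to the shared variable groups; rows normalized to sum 1.
.voting_network <- function(x) {
  rx <- apply(x, 2, rank)       # rank within each cell -> Spearman basis
  cc <- stats::cor(rx)
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  cc <- pmax(cc, 0)
  rs <- rowSums(cc)
  rs[rs == 0] <- 1
  cc / rs
}

#' Cross-species cluster homology by neighbor voting
#'
#' Re-implementation of the neighbor-voting replicability procedure: both
#' datasets are combined over shared (variable) ortholog groups, a
#' cell-cell Spearman correlation network is built and row-normalized into
#' voting weights, each training cluster's labels are propagated across the
#' network, and the AUROC of the received votes for each test cluster's
#' cells is recorded. The reported map averages the two directions
#' (train on A, test on B; train on B, test on A).
#'
#' @param mat_a,mat_b groups x cells matrices on a shared group space.
#' @param clusters_a,clusters_b per-cell cluster labels.
#' @param variable_groups groups used for the correlation network; default
#'   selects them by variance-stabilized ranking on the combined matrix.
#' @param n_var number of variable groups when auto-selecting.
#' @return matrix of AUROCs, rows = clusters of A, columns = clusters of B.
#' @export
neighbor_voting_auroc <- function(mat_a, clusters_a, mat_b, clusters_b,
                                  variable_groups = NULL, n_var = 500L) {
  shared <- intersect(rownames(mat_a), rownames(mat_b))
  if (length(shared) == 0L) stop("no shared groups")
  a <- mat_a[shared, , drop = FALSE]
  b <- mat_b[shared, , drop = FALSE]
  ka <- sort(unique(clusters_a)); kb <- sort(unique(clusters_b))
  sz <- c(table(clusters_a), table(clusters_b))
  if (any(sz < 5L)) stop("every cluster needs at least 5 cells")
  combined <- as.matrix(methods::cbind2(a, b))
  if (is.null(variable_groups)) {
    sp <- methods::as(methods::as(Matrix::Matrix(combined, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
    rownames(sp) <- shared
    variable_groups <- select_variable_genes(sp, n_top = n_var)
  }
  x <- combined[intersect(variable_groups, shared), , drop = FALSE]
  if (any(apply(x, 2, stats::sd) == 0))
    stop("constant cells in the shared group space")
  W <- .voting_network(x)
  na <- ncol(a); nb <- ncol(b)
  idx_a <- seq_len(na); idx_b <- na + seq_len(nb)

  vote_auroc <- function(train_idx, train_labels, test_idx, test_labels,
                         train_k, test_k) {
    out <- matrix(NA_real_, length(train_k), length(test_k))
    for (ti in seq_along(train_k)) {
      lab <- as.numeric(train_labels == train_k[ti])
      votes <- W[test_idx, train_idx, drop = FALSE] %*% lab
      for (si in seq_along(test_k)) {
        a <- .auroc(as.numeric(votes), test_labels == test_k[si])
        # a test species with one single cluster is trivially recovered
        out[ti, si] <- if (is.na(a)) 1 else a
      }
    }
    out
  }
  ab <- vote_auroc(idx_a, clusters_a, idx_b, clusters_b, ka, kb)
  ba <- vote_auroc(idx_b, clusters_b, idx_a, clusters_a, kb, ka)
  res <- (ab + t(ba)) / 2
  rownames(res) <- as.character(ka)
  colnames(res) <- as.character(kb)
  res
}

#' Per-cluster gene-set co-expression call
#'
#' Scores every cell for the gene set (background-matched module score),
#' averages per cluster, and classifies the species as co-expressing the
#' set ("co-expressed": some cluster exceeds the permutation null quantile
#' and a strict majority of the set's genes are individually enriched in
#' that same cluster), "spread" (genes individually enriched but across at
#' least two disjoint clusters with no single qualifying cluster), or
#' "absent".
#' Sets covering fewer than 3 groups are "not evaluable".
#'
#' @param mat groups x cells expression (raw counts; normalized
#'   internally).
#' @param clusters per-cell cluster labels.
#' @param gene_set character vector of group ids.
#' @param null_quantile permutation-null quantile a cluster mean must
#'   exceed (default 0.99).
#' @param n_perm random sets drawn for the null (default 200).
#' @param fdr per-gene enrichment FDR.
#' @param seed integer seed.
#' @return list of class \code{coexpression_call}: \code{call},
#'   \code{cluster_scores}, \code{top_cluster}, \code{enriched_by_gene}.
#' @export
geneset_enrichment_by_cluster <- function(mat, clusters, gene_set,
                                          null_quantile = 0.99,
                                          n_perm = 200L, fdr = 0.05,
                                          seed = 1L) {
  present <- intersect(gene_set, rownames(mat))
  if (length(present) < 3L)
    return(structure(list(call = "not evaluable",
                          cluster_scores = NULL, top_cluster = NA,
                          enriched_by_gene = NULL),
                     class = "coexpression_call"))
  set.seed(seed)
  norm <- normalize_counts(mat)
  ks <- sort(unique(clusters))
  sc <- module_score(norm, present, seed = seed)
  cl_mean <- vapply(ks, function(k) mean(sc[clusters == k]), numeric(1))
  names(cl_mean) <- as.character(ks)
  # permutation null: random sets of the same size
  null_means <- matrix(NA_real_, n_perm, length(ks))
  for (p in seq_len(n_perm)) {
    rs <- sample(rownames(mat), length(present))
    s0 <- module_score(norm, rs, seed = seed + p)
    null_means[p, ] <- vapply(ks, function(k) mean(s0[clusters == k]),
                              numeric(1))
  }
  thr <- apply(null_means, 2, stats::quantile, probs = null_quantile)
  qualifying <- which(cl_mean > thr)

  # per-gene enrichment: cluster where the gene's signed AUROC is largest,
  # one-sided rank test there, BH-corrected across the set's genes
  enriched_cluster <- rep(NA, length(present))
  names(enriched_cluster) <- present
  best_k <- integer(length(present))
  gene_p <- numeric(length(present))
  for (gi in seq_along(present)) {
    v <- norm[present[gi], ]
    aucs <- vapply(ks, function(k) .auroc(as.numeric(v), clusters == k),
                   numeric(1))
    k_best <- ks[which.max(aucs)]
    best_k[gi] <- k_best
    gene_p[gi] <- stats::wilcox.test(as.numeric(v[clusters == k_best]),
                                     as.numeric(v[clusters != k_best]),
                                     alternative = "greater",
                                     exact = FALSE)$p.value
  }
  # Bonferroni over the best-cluster selection, then BH across genes
  gene_q <- stats::p.adjust(pmin(1, gene_p * length(ks)), method = "BH")
  enriched_cluster[gene_q < fdr] <- best_k[gene_q < fdr]
  call <- "absent"
  top <- if (length(qualifying)) ks[qualifying[which.max(cl_mean[qualifying])]]
         else NA
  if (length(qualifying) > 0L) {
    n_in_top <- sum(enriched_cluster == top, na.rm = TRUE)
    if (n_in_top > length(present) / 2) call <- "co-expressed"
  }
  if (call != "co-expressed") {
    hit_clusters <- unique(stats::na.omit(enriched_cluster))
    if (length(hit_clusters) >= 2L) call <- "spread"
  }
  structure(list(call = call, cluster_scores = cl_mean,
                 top_cluster = top, enriched_by_gene = enriched_cluster),
            class = "coexpression_call")
}

#' @export
print.coexpression_call <- function(x, ...) {
  cat("co-expression call:", x$call)
  if (!is.na(x$top_cluster)) cat(" (top cluster ", x$top_cluster, ")",
                                 sep = "")
  cat("\n")
  invisible(x)
}
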