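#' Cluster-based similarity partitioning (CSPA) consensus matrix
#'
#' Combines an ensemble of labelings into a cell-by-cell co-clustering
#' frequency matrix: entry (i, j) is the fraction of ensemble runs that
#' placed cells i and j in the same cluster.
#'
#' @param labelings list of labelings as returned by
#'   \code{\link{run_base_clusterings}} (each with a \code{labels} vector
#'   over the same cells).
#' @return object of class \code{consensus_matrix}: list with \code{M}
#'   (symmetric matrix, unit diagonal) and \code{n_runs}.
#' @export
cspa_consensus <- function(labelings) {
  if (length(labelings) < 2L) stop("need at least 2 labelings")
  lens <- vapply(labelings, function(l) length(l$labels), integer(1))
  if (length(unique(lens)) != 1L)
    stop("labelings cover different cell sets")
  n <- lens[1L]
  M <- matrix(0, n, n)
  for (l in labelings) {
    lab <- l$labels
    M <- M + outer(lab, lab, "==")
  }
  M <- M / length(labelings)
  structure(list(M = M, n_runs = length(labelings)),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("consensus_matrix:", nrow(x$M), "cells,", x$n_runs, "ensemble runs\n")
  invisible(x)
}

#' Cut the consensus matrix into robust clusters
#'
#' Average-linkage hierarchical clustering on the co-clustering distance
#' \eqn{1 - M}, cut at a conservative height: the default 0.2 requires at
#' least 80\% co-clustering within cluster cores.
#'
#' @param consensus a \code{\link{cspa_consensus}} result.
#' @param height cut height in (0, 1); default 0.2.
#' @return labeling list: \code{method = "consensus"}, dense \code{labels},
#'   and the retained \code{dendrogram} (hclust) for audit and for sibling
#'   detection during merging.
#' @export
cut_consensus <- function(consensus, height = 0.2) {
  M <- consensus$M
  if (any(!is.finite(M))) stop("non-finite consensus entries")
  if (height <= 0 || height >= 1) stop("height must be in (0, 1)")
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  # guard against tiny floating-point inversions in the merge heights
  hc$height <- cummax(hc$height)
  raw <- stats::cutree(hc, h = height)
  list(method = "consensus", seed = NA_integer_,
       labels = .dense_labels(raw), dendrogram = hc, height = height)
}

# average-linkage tree over cluster centroids in co-clustering space,
# used to define "neighboring" (sibling) cluster pairs deterministically
.cluster_sibling_pairs <- function(M, labels) {
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2L) return(NULL)
  # mean co-clustering between clusters
  S <- matrix(0, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    S[a, b] <- mean(M[labels == ks[a], labels == ks[b], drop = FALSE])
  }
  hc <- stats::hclust(stats::as.dist(1 - S), method = "average")
  merges <- list()
  # sibling pairs = pairs of singleton subtrees joined directly, ordered by
  # merge height (ascending): the most similar pairs are tested first
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1L]; b <- hc$merge[m, 2L]
    if (a < 0 && b < 0)
      merges[[length(merges) + 1L]] <-
        list(pair = c(ks[-a], ks[-b]), height = hc$height[m])
  }
  if (length(merges) == 0L) return(NULL)
  ord <- order(vapply(merges, `[[`, numeric(1), "height"))
  lapply(merges[ord], `[[`, "pair")
}

#' Merge indistinct neighboring clusters by differential expression
#'
#' Iteratively tests dendrogram-sibling cluster pairs with the module-wide
#' DE criterion (Wilcoxon rank-sum, BH-FDR 0.05, |log2FC| >= 0.25) and
#' merges pairs with fewer than \code{min_de_genes} significant genes,
#' repeating until a fixed point. The cluster count never increases.
#'
#' @param counts genes x cells raw counts.
#' @param labeling labeling from \code{\link{cut_consensus}}.
#' @param consensus the \code{\link{cspa_consensus}} used for the cut (for
#'   sibling detection); optional, falls back to centroid similarity on
#'   normalized expression.
#' @param min_de_genes merge when strictly fewer DE genes than this
#'   (default 10; 0 disables merging).
#' @param fdr,min_log2fc DE criterion.
#' @param genes optional gene subset for testing (default variable genes).
#' @return updated labeling with a \code{merge_log} attribute.
#' @export
merge_by_de <- function(counts, labeling, consensus = NULL,
                        min_de_genes = 10L, fdr = 0.05, min_log2fc = 0.25,
                        genes = NULL) {
  labels <- labeling$labels
  if (min_de_genes <= 0L) return(labeling)
  norm <- normalize_counts(counts)
  if (is.null(genes)) genes <- select_variable_genes(counts, n_top = 2000L)
  x <- norm[intersect(genes, rownames(norm)), , drop = FALSE]
  M <- if (!is.null(consensus)) consensus$M else {
    emb <- t(as.matrix(x))
    stats::cor(t(emb))   # cell-cell correlation as similarity fallback
  }
  log <- list()
  repeat {
    pairs <- .cluster_sibling_pairs(M, labels)
    if (is.null(pairs)) break
    merged <- FALSE
    for (p in pairs) {
      i1 <- which(labels == p[1L]); i2 <- which(labels == p[2L])
      if (length(i1) == 0L || length(i2) == 0L) next
      de <- .de_genes(x, i1, i2, fdr, min_log2fc)
      n_de <- sum(de$significant)
      if (n_de < min_de_genes) {
        labels[labels == p[2L]] <- p[1L]
        log[[length(log) + 1L]] <- c(kept = p[1L], merged = p[2L],
                                     n_de = n_de)
        merged <- TRUE
        break   # recompute siblings after each merge
      }
    }
    if (!merged) break
  }
  out <- labeling
  out$labels <- .dense_labels(labels)
  attr(out, "merge_log") <- log
  out
}

#' Greedy boolean marker gate for one cluster
#'
#' Searches for a small conjunction of (gene, direction, threshold) terms
#' that best identifies the cluster against all other cells, in the spirit
#' of flow-cytometry-style hypergating: at each step the term maximizing the
#' gate's F1 is added, with thresholds searched over the gene's expression
#' deciles, stopping when the F1 gain drops below \code{min_gain} or
#' \code{max_terms} is reached.
#'
#' @param normalized genes x cells normalized expression.
#' @param labels per-cell cluster labels.
#' @param cluster cluster id to gate.
#' @param max_terms maximum number of gate terms (default 4).
#' @param min_gain minimum F1 improvement to accept a term (default 0.01).
#' @param genes optional gene subset searched (default all genes).
#' @param n_candidates the threshold search is restricted to this many
#'   genes, pre-ranked by absolute signed AUROC for the cluster (keeps the
#'   decile search tractable without changing which markers win).
#' @return object of class \code{marker_gate}: \code{cluster}, \code{terms}
#'   (data.frame gene/direction/threshold), \code{F1}.
#' @export
find_marker_gate <- function(normalized, labels, cluster, max_terms = 4L,
                             min_gain = 0.01, genes = NULL,
                             n_candidates = 100L) {
  y <- labels == cluster
  if (!any(y)) stop("cluster ", cluster, " is empty")
  x <- if (is.null(genes)) normalized
       else normalized[intersect(genes, rownames(normalized)), ,
                       drop = FALSE]
  x <- as.matrix(x)
  if (nrow(x) > n_candidates) {
    sa <- abs(gene_signed_auroc(x, y))
    x <- x[order(sa, decreasing = TRUE)[seq_len(n_candidates)], ,
           drop = FALSE]
  }
  n <- ncol(x)
  f1 <- function(pred) {
    tp <- sum(pred & y)
    if (tp == 0L) return(0)
    2 * tp / (sum(pred) + sum(y))
  }
  inside <- rep(TRUE, n)   # cells satisfying the gate so far
  terms <- data.frame(gene = character(0), direction = character(0),
                      threshold = numeric(0), stringsAsFactors = FALSE)
  best_f1 <- f1(inside)
  probs <- seq(0.1, 0.9, by = 0.1)
  for (step in seq_len(max_terms)) {
    cand <- NULL
    for (gi in seq_len(nrow(x))) {
      v <- x[gi, ]
      qs <- unique(stats::quantile(v, probs))
      for (thr in qs) for (dir in c("+", "-")) {
        pred <- inside & (if (dir == "+") v > thr else v <= thr)
        sc <- f1(pred)
        if (is.null(cand) || sc > cand$f1)
          cand <- list(gene = rownames(x)[gi], direction = dir,
                       threshold = unname(thr), f1 = sc, pred = pred)
      }
    }
    if (is.null(cand) || cand$f1 < best_f1 + min_gain) break
    terms <- rbind(terms, data.frame(gene = cand$gene,
                                     direction = cand$direction,
                                     threshold = cand$threshold,
                                     stringsAsFactors = FALSE))
    inside <- cand$pred
    best_f1 <- cand$f1
  }
  structure(list(cluster = cluster, terms = terms, F1 = best_f1),
            class = "marker_gate")
}

#' @export
print.marker_gate <- function(x, ...) {
  cat("marker_gate for cluster", x$cluster, "(F1 =",
      sprintf("%.3f", x$F1), ")\n")
  if (nrow(x$terms))
    for (i in seq_len(nrow(x$terms)))
      cat(" ", x$terms$gene[i], x$terms$direction[i],
          sprintf("%.3f", x$terms$threshold[i]), "\n")
  invisible(x)
}

#' Validate clusters by re-identification AUROC on gate genes
#'
#' Trains a ridge-regularized linear score on the gate genes only, with
#' k-fold cross-validation, and reports the held-out AUROC for
#' re-identifying each cluster. A cluster passes when its AUROC exceeds
#' \code{auroc_min} (default 0.7), indicating it can be re-identified from
#' a handful of genes.
#'
#' @param normalized genes x cells normalized expression.
#' @param labels per-cell cluster labels.
#' @param gates list of \code{\link{find_marker_gate}} results (one per
#'   cluster).
#' @param auroc_min pass threshold.
#' @param folds cross-validation folds (reduced with a warning for clusters
#'   smaller than 10 cells).
#' @param seed seed for fold assignment.
#' @return data.frame: cluster, auroc, pass.
#' @export
validate_cluster_auroc <- function(normalized, labels, gates,
                                   auroc_min = 0.7, folds = 5L, seed = 1L) {
  set.seed(seed)
  rows <- lapply(gates, function(g) {
    y <- as.integer(labels == g$cluster)
    genes <- unique(g$terms$gene)
    if (length(genes) == 0L)
      return(data.frame(cluster = g$cluster, auroc = 0.5, pass = FALSE))
    X <- t(as.matrix(normalized[genes, , drop = FALSE]))
    kf <- folds
    if (sum(y) < 10L) {
      warning("cluster ", g$cluster, " has fewer than 10 cells; folds reduced")
      kf <- max(2L, min(folds, sum(y)))
    }
    fold <- sample(rep_len(seq_len(kf), length(y)))
    score <- numeric(length(y))
    lambda <- 1e-3
    for (f in seq_len(kf)) {
      tr <- fold != f
      Xt <- cbind(1, X[tr, , drop = FALSE])
      beta <- solve(crossprod(Xt) + lambda * diag(ncol(Xt)),
                    crossprod(Xt, y[tr]))
      score[!tr] <- cbind(1, X[!tr, , drop = FALSE]) %*% beta
    }
    a <- .auroc(score, y == 1L)
    data.frame(cluster = g$cluster, auroc = a, pass = a > auroc_min)
  })
  do.call(rbind, rows)
}

#' End-to-end consensus clustering
#'
#' Convenience wrapper: normalize, select variable genes and PCs, build the
#' shared-neighbor graph, run the base ensemble, form the CSPA consensus,
#' cut robust clusters and merge indistinct siblings.
#'
#' @param counts genes x cells raw counts.
#' @param k neighbors for the graph.
#' @param n_pcs principal components used for the embedding.
#' @param n_var variable genes.
#' @param methods base clusterers (see \code{\link{run_base_clusterings}}).
#' @param seeds ensemble seeds.
#' @param height consensus cut height.
#' @param min_de_genes sibling-merge threshold.
#' @param seed global seed.
#' @return list: \code{labels} (final dense labels), \code{consensus},
#'   \code{labelings}, \code{embedding}.
#' @export
consensus_cluster <- function(counts, k = 20L, n_pcs = 20L, n_var = 2000L,
                              methods = c("slm", "louvain", "walktrap",
                                          "density_peaks", "gmm"),
                              seeds = 1L, height = 0.2, min_de_genes = 10L,
                              seed = 1L) {
  set.seed(seed)
  norm <- normalize_counts(counts)
  vg <- select_variable_genes(counts, n_top = n_var)
  pca <- run_pca(norm, genes = vg, n_pcs = n_pcs)
  graph <- build_knn_graph(pca$scores, k = k)
  labelings <- run_base_clusterings(graph, pca$scores, methods = methods,
                                    seeds = seeds)
  cons <- cspa_consensus(labelings)
  cut <- cut_consensus(cons, height = height)
  final <- merge_by_de(counts, cut, consensus = cons,
                       min_de_genes = min_de_genes, genes = vg)
  list(labels = final$labels, consensus = cons, labelings = labelings,
       embedding = pca$scores, variable_genes = vg)
}
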