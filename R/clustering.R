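#' Build a weighted k-nearest-neighbor graph
#'
#' Exact Euclidean kNN on an embedding, with shared-nearest-neighbor edge
#' weights computed either as the Jaccard overlap of the two kNN sets
#' (Phenograph style) or from the rank of the closest shared neighbor
#' (SNN-Cliq style: \eqn{1 - } average rank of the closest shared neighbor
#' \eqn{/ k}; 0 when no neighbor is shared). Edges with weight 0 are
#' dropped; weights are symmetrized by the maximum.
#'
#' @param embedding cells x dims numeric matrix.
#' @param k number of neighbors (excluding the cell itself).
#' @param weighting \code{"phenograph_jaccard"} or \code{"snn_cliq"}.
#' @return list of class \code{neighbor_graph}: \code{graph} (weighted
#'   undirected igraph), \code{knn} (cells x k neighbor index matrix),
#'   \code{k}, \code{weighting}.
#' @export
build_knn_graph <- function(embedding, k = 20L,
                            weighting = c("phenograph_jaccard", "snn_cliq")) {
  weighting <- match.arg(weighting)
  n <- nrow(embedding)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  knn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))

  # candidate edges: i -- each of its neighbors
  ii <- rep(seq_len(n), each = k)
  jj <- as.integer(t(knn))
  pair <- cbind(pmin(ii, jj), pmax(ii, jj))
  pair <- unique(pair)

  nbr_sets <- lapply(seq_len(n), function(i) knn[i, ])
  w <- vapply(seq_len(nrow(pair)), function(e) {
    i <- pair[e, 1L]; j <- pair[e, 2L]
    si <- nbr_sets[[i]]; sj <- nbr_sets[[j]]
    shared <- intersect(si, sj)
    if (weighting == "phenograph_jaccard") {
      length(shared) / length(union(si, sj))
    } else {
      if (length(shared) == 0L) return(0)
      ri <- match(shared, si); rj <- match(shared, sj)
      1 - min((ri + rj) / 2) / k
    }
  }, numeric(1))
  keep <- w > 0
  g <- igraph::graph_from_edgelist(pair[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  if (!is.null(rownames(embedding)))
    igraph::V(g)$name <- rownames(embedding)
  structure(list(graph = g, knn = knn, k = as.integer(k),
                 weighting = weighting),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", igraph::vcount(x$graph), "cells,",
      igraph::ecount(x$graph), "edges, k =", x$k,
      ", weighting =", x$weighting, "\n")
  invisible(x)
}

# --- density peaks (Rodriguez & Laio style), decision automated by the
# gamma = rho * delta outlier rule with a gap statistic on the sorted gammas.
.density_peaks <- function(embedding, dc = NULL, max_centers = 15L) {
  n <- nrow(embedding)
  d <- as.matrix(stats::dist(embedding))
  if (is.null(dc)) dc <- stats::quantile(d[upper.tri(d)], 0.02)
  if (dc <= 0) dc <- mean(d[upper.tri(d)]) / 10
  rho <- rowSums(exp(-(d / dc)^2)) - 1     # gaussian kernel density
  delta <- numeric(n)
  nn_higher <- integer(n)
  ord <- order(rho, decreasing = TRUE)
  delta[ord[1L]] <- max(d[ord[1L], ])
  nn_higher[ord[1L]] <- ord[1L]
  for (r in 2:n) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    jbest <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, jbest]
    nn_higher[i] <- jbest
  }
  gamma <- rho * delta
  gs <- sort(gamma, decreasing = TRUE)
  k_max <- min(max_centers, n - 1L)
  gaps <- gs[seq_len(k_max)] - gs[seq_len(k_max) + 1L]
  # relative gap: centers separated from the continuum of ordinary points
  n_centers <- which.max(gaps / (gs[seq_len(k_max) + 1L] + 1e-12))
  centers <- order(gamma, decreasing = TRUE)[seq_len(n_centers)]
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_len(n_centers)
  for (i in ord) if (is.na(labels[i])) labels[i] <- labels[nn_higher[i]]
  labels
}

#' Run the base clustering ensemble
#'
#' Runs each requested base clusterer and returns one labeling per
#' (method, seed). Graph methods (SLM-family modularity partitioning via
#' Leiden, multilevel Louvain, walktrap, spinglass) run on the weighted
#' shared-neighbor graph; density peaks and the Gaussian mixture (with
#' BIC-selected component count) run on the embedding. A single method
#' failing is recorded as a warning, not an error.
#'
#' @param graph a \code{\link{build_knn_graph}} result.
#' @param embedding cells x dims matrix (for density peaks / GMM).
#' @param methods subset of \code{c("slm", "louvain", "walktrap",
#'   "spinglass", "density_peaks", "gmm")}.
#' @param seeds integer vector of seeds; each method is run once per seed.
#' @param gmm_max_components upper bound on mixture components.
#' @param embed_dims the embedding-based methods (density peaks, Gaussian
#'   mixture) use only this many leading embedding columns: kernel density
#'   estimates and covariance models degrade in high dimensions while the
#'   leading components carry the cluster structure.
#' @return list of labelings; each has \code{method}, \code{seed},
#'   \code{labels} (dense integers 0..K-1).
#' @export
run_base_clusterings <- function(graph, embedding,
                                 methods = c("slm", "louvain", "walktrap",
                                             "density_peaks", "gmm"),
                                 seeds = 1L, gmm_max_components = 12L,
                                 embed_dims = 8L) {
  if (length(methods) < 2L) stop("need at least 2 methods for an ensemble")
  g <- graph$graph
  embedding <- embedding[, seq_len(min(embed_dims, ncol(embedding))),
                         drop = FALSE]
  out <- list()
  for (m in methods) for (s in seeds) {
    lab <- tryCatch({
      set.seed(s)
      raw <- switch(m,
        slm = igraph::membership(igraph::cluster_leiden(
          g, objective_function = "modularity", n_iterations = 5)),
        louvain = igraph::membership(igraph::cluster_louvain(g)),
        walktrap = igraph::membership(igraph::cluster_walktrap(g)),
        spinglass = igraph::membership(igraph::cluster_spinglass(g)),
        density_peaks = .density_peaks(embedding),
        gmm = {
          fit <- mclust::Mclust(embedding,
                                G = seq_len(gmm_max_components),
                                verbose = FALSE)
          fit$classification
        },
        stop("unknown method: ", m))
      .dense_labels(as.integer(raw))
    }, error = function(e) {
      warning("base clusterer '", m, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(lab))
      out[[length(out) + 1L]] <- list(method = m, seed = s, labels = lab)
  }
  out
}

#' Mock-doublet detection
#'
#' Generates artificial doublets by summing the counts of randomly chosen
#' cell pairs (rescaled to the mean parental depth), co-embeds them with the
#' real cells, and scores each real cell by the fraction of its k nearest
#' neighbors that are mock doublets. Real doublets sit between clusters
#' where mocks concentrate, so their score is high.
#'
#' @param counts genes x cells raw counts.
#' @param n_mock number of artificial doublets (a common choice is one per
#'   real cell).
#' @param k neighbors used for the score.
#' @param neighbor_frac_threshold flag cells whose score exceeds this value;
#'   the default is the overall mock fraction, the score a cell sitting in
#'   a pure doublet neighborhood would centre on.
#' @param n_pcs principal components for the co-embedding; \code{NULL}
#'   (default) keeps components explaining over 1\% of the variance.
#' @param n_var variable genes for the co-embedding.
#' @param seed integer seed.
#' @return data.frame with \code{cell_id}, \code{score}, \code{flagged}.
#' @export
detect_doublets_mock <- function(counts, n_mock = ncol(counts), k = 30L,
                                 neighbor_frac_threshold = NULL,
                                 n_pcs = NULL, n_var = 1000L, seed = 1L) {
  n <- ncol(counts)
  if (n_mock < 1L) stop("n_mock must be at least 1")
  if (n_mock >= n^2) stop("n_mock must be below n_cells^2")
  set.seed(seed)
  p1 <- sample.int(n, n_mock, replace = TRUE)
  p2 <- vapply(p1, function(i) sample(setdiff(seq_len(n), i), 1L), integer(1))
  mock <- counts[, p1, drop = FALSE] + counts[, p2, drop = FALSE]
  depth <- Matrix::colSums(counts)
  target <- (depth[p1] + depth[p2]) / 2
  scl <- pmin(target / Matrix::colSums(mock), 1)
  # rescale to the mean parental depth by binomial thinning: preserves the
  # count statistics of a genuinely shallower library (a hard round() would
  # erase summed 1-counts and displace mocks along the detection axis)
  mock <- methods::as(methods::as(mock, "generalMatrix"), "CsparseMatrix")
  col_of <- rep.int(seq_len(n_mock), diff(mock@p))
  mock@x <- as.numeric(stats::rbinom(length(mock@x), size = mock@x,
                                     prob = scl[col_of]))
  mock <- Matrix::drop0(mock)
  colnames(mock) <- sprintf("mock%d", seq_len(n_mock))
  combined <- methods::cbind2(counts, mock)

  norm <- normalize_counts(combined)
  vg <- select_variable_genes(counts[, seq_len(n)], n_top = n_var)
  pca <- run_pca(norm, genes = vg, n_pcs = if (is.null(n_pcs)) 30L
                                           else n_pcs)
  emb <- pca$scores
  if (is.null(n_pcs)) {
    keep_pc <- which(pca$var_share > 0.01)
    if (length(keep_pc) < 2L) keep_pc <- 1:2
    emb <- emb[, keep_pc, drop = FALSE]
  }

  d <- as.matrix(stats::dist(emb))
  diag(d) <- Inf
  is_mock <- c(rep(FALSE, n), rep(TRUE, n_mock))
  score <- vapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    mean(is_mock[nb])
  }, numeric(1))
  mock_frac <- n_mock / (n + n_mock)
  if (is.null(neighbor_frac_threshold))
    neighbor_frac_threshold <- mock_frac
  data.frame(cell_id = colnames(counts), score = score,
             flagged = score > neighbor_frac_threshold,
             stringsAsFactors = FALSE)
}

#' Detect clusters that look like mixtures of two other clusters
#'
#' For every cluster C and ordered pair of other clusters (A, B), counts the
#' genes differentially expressed between C and the pooled A+B cells that
#' are not also differentially expressed between A and B in the same
#' direction ("unique" DE genes), and locates C's centroid relative to the
#' A--B segment. Clusters with near-zero unique DE genes for some pair and a
#' centroid projecting inside the segment are reported as doublet-cluster
#' candidates.
#'
#' @param counts genes x cells raw counts (normalized internally).
#' @param labels per-cell integer cluster labels (dense 0..K-1).
#' @param max_unique_de report a cluster when its best parent pair has at
#'   most this many unique DE genes (default 10).
#' @param fdr,min_log2fc DE criterion (module-wide defaults).
#' @param genes optional gene subset to test (default: variable genes).
#' @return data.frame, one row per tested cluster: cluster, best parent
#'   pair, unique DE count, projection parameter, candidate flag.
#' @export
doublet_cluster_test <- function(counts, labels, max_unique_de = 10L,
                                 fdr = 0.05, min_log2fc = 0.25,
                                 genes = NULL) {
  ks <- sort(unique(labels))
  if (length(ks) < 3L) {
    return(data.frame(cluster = integer(0), parent_a = integer(0),
                      parent_b = integer(0), unique_de = integer(0),
                      projection = numeric(0), candidate = logical(0)))
  }
  norm <- normalize_counts(counts)
  if (is.null(genes)) genes <- select_variable_genes(counts, n_top = 1000L)
  x <- norm[intersect(genes, rownames(norm)), , drop = FALSE]
  sizes <- table(factor(labels, levels = ks))
  centroids <- vapply(ks, function(k)
    Matrix::rowMeans(x[, labels == k, drop = FALSE]), numeric(nrow(x)))
  de_pair <- new.env(parent = emptyenv())   # cache of A-vs-B tests
  get_de_ab <- function(a, b) {
    key <- paste(a, b, sep = "_")
    if (is.null(de_pair[[key]]))
      de_pair[[key]] <- .de_genes(x, which(labels == a), which(labels == b),
                                  fdr, min_log2fc)
    de_pair[[key]]
  }
  rows <- list()
  for (c_idx in seq_along(ks)) {
    cl <- ks[c_idx]
    if (sizes[c_idx] < 3L) { warning("cluster ", cl, " too small, skipped")
                             next }
    others <- ks[ks != cl & sizes[as.character(ks)] >= 3]
    if (length(others) < 2L) next
    best <- NULL
    for (ai in seq_along(others)) for (bi in seq_along(others)) {
      if (bi <= ai) next
      a <- others[ai]; b <- others[bi]
      de_ab <- get_de_ab(a, b)
      de_cab <- .de_genes(x, which(labels == cl),
                          which(labels %in% c(a, b)), fdr, min_log2fc)
      # unique: DE in C-vs-(A+B) but not DE same-direction in A-vs-B
      shared_dir <- de_ab$significant &
        sign(de_ab$log2fc) == sign(de_cab$log2fc)
      uniq <- sum(de_cab$significant & !shared_dir)
      # centroid projection on the A-B segment
      va <- centroids[, ks == a]; vb <- centroids[, ks == b]
      vc <- centroids[, c_idx]
      seg <- vb - va
      tproj <- sum((vc - va) * seg) / sum(seg^2)
      if (is.null(best) || uniq < best$unique_de)
        best <- list(parent_a = a, parent_b = b, unique_de = uniq,
                     projection = tproj)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, parent_a = best$parent_a, parent_b = best$parent_b,
      unique_de = best$unique_de, projection = best$projection,
      candidate = best$unique_de <= max_unique_de &
        best$projection >= 0 & best$projection <= 1)
  }
  do.call(rbind, rows)
}
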