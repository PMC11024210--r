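# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: set operations over all pairs, Prufer-sequence
# enumeration of spanning trees, direct pair counting.

# AUC by exhaustive enumeration of (target, non-target) cell pairs:
# (#concordant + 0.5 #ties) / total.
oracle_pair_auc <- function(score, positive) {
  pos <- score[positive]; neg <- score[!positive]
  conc <- 0; ties <- 0
  for (a in pos) for (b in neg) {
    if (a > b) conc <- conc + 1 else if (a == b) ties <- ties + 1
  }
  (conc + 0.5 * ties) / (length(pos) * length(neg))
}

# co-clustering matrix by direct pair counting over runs
oracle_coclust <- function(label_list) {
  n <- length(label_list[[1]])
  M <- matrix(0, n, n)
  for (lab in label_list)
    for (i in seq_len(n)) for (j in seq_len(n))
      M[i, j] <- M[i, j] + (lab[i] == lab[j])
  M / length(label_list)
}

# decode a Prufer sequence into a tree edge list on n nodes
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  e <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    e <- e + 1L
    edges[e, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1L, ] <- last
  edges
}

# minimum spanning tree by exhaustive enumeration of all n^(n-2) labeled
# spanning trees (Cayley/Prufer); returns the along-tree path-length matrix
oracle_mst_paths <- function(points) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best_w <- Inf; best_edges <- NULL
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_to_edges(seqs[r, ], n)
    w <- sum(d[ed])
    if (w < best_w) { best_w <- w; best_edges <- ed }
  }
  # path lengths along the best tree via repeated relaxation
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (e in seq_len(n - 1L)) {
    i <- best_edges[e, 1L]; j <- best_edges[e, 2L]
    D[i, j] <- D[j, i] <- d[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  list(D = D, weight = best_w, edges = best_edges)
}

# Cliff's delta by explicit enumeration of all pairs
oracle_cliffs_delta <- function(x, y) {
  gt <- 0; lt <- 0
  for (a in x) for (b in y) {
    if (a > b) gt <- gt + 1 else if (a < b) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# brute-force kNN graph weights over all pairs
oracle_knn_weights <- function(embedding, k, weighting) {
  n <- nrow(embedding)
  d <- as.matrix(stats::dist(embedding)); diag(d) <- Inf
  nbr <- lapply(seq_len(n), function(i) order(d[i, ])[seq_len(k)])
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- intersect(nbr[[i]], nbr[[j]])
    W[i, j] <- if (weighting == "phenograph_jaccard")
      length(shared) / length(union(nbr[[i]], nbr[[j]]))
    else if (length(shared) == 0L) 0
    else 1 - min((match(shared, nbr[[i]]) + match(shared, nbr[[j]])) / 2) / k
  }
  W
}
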