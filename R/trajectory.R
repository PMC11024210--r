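#' Diffusion-map embedding
#'
#' Gaussian-kernel diffusion map with local bandwidth: the kernel uses each
#' cell's distance to its \code{k_sigma}-th neighbor as a local sigma,
#' row-normalizes the transition matrix, and returns the leading non-trivial
#' eigenvectors scaled by their eigenvalues. When the kernel graph is
#' effectively disconnected, components are reconnected through the
#' symmetric kNN union with a warning.
#'
#' @param normalized genes x cells normalized expression.
#' @param variable_genes gene subset to embed on.
#' @param n_components number of diffusion components (>= 1).
#' @param k_sigma neighbor rank used for the local bandwidth.
#' @return cells x n_components matrix of diffusion coordinates.
#' @export
diffusion_map <- function(normalized, variable_genes = rownames(normalized),
                          n_components = 10L, k_sigma = 10L) {
  if (n_components < 1L) stop("n_components must be at least 1")
  x <- t(as.matrix(normalized[intersect(variable_genes,
                                        rownames(normalized)), ,
                              drop = FALSE]))
  n <- nrow(x)
  if (n < n_components + 1L) stop("need more cells than components")
  d <- as.matrix(stats::dist(x))
  sig <- apply(d, 1, function(row) sort(row)[k_sigma + 1L])
  sig[sig == 0] <- min(sig[sig > 0], 1e-12)
  K <- exp(-d^2 / outer(sig, sig))
  # reconnect if the thresholded kernel graph falls apart
  adj <- K > 1e-12
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max", diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning("kernel graph disconnected; reconnecting via kNN union")
    knn <- t(apply(d, 1, function(row) order(row)[2:(k_sigma + 1L)]))
    for (i in seq_len(n)) for (j in knn[i, ]) {
      K[i, j] <- max(K[i, j], 1e-6)
      K[j, i] <- K[i, j]
    }
  }
  deg <- rowSums(K)
  M <- K / sqrt(outer(deg, deg))          # symmetric conjugate of D^-1 K
  eig <- eigen(M, symmetric = TRUE)
  psi <- eig$vectors / sqrt(deg)          # row-stochastic eigenvectors
  comp_idx <- 2:(n_components + 1L)
  out <- sweep(psi[, comp_idx, drop = FALSE], 2, eig$values[comp_idx], "*")
  rownames(out) <- colnames(normalized)
  colnames(out) <- sprintf("DC%d", seq_len(n_components))
  out
}

#' Averaged along-tree distances over bootstrapped minimum spanning trees
#'
#' Repeatedly subsamples a fraction of the cells without replacement, builds
#' the Euclidean minimum spanning tree of the subsample, and records the
#' pairwise path lengths along the tree. The returned distance is the
#' average over the trees in which both cells were present; pairs never
#' co-sampled (possible at small \code{n_trees}) are imputed by shortest
#' paths through the observed-distance graph, which converges to a no-op as
#' \code{n_trees} grows.
#'
#' @param embedding cells x dims coordinates (e.g. diffusion components).
#' @param n_trees number of bootstrapped trees (default 1000).
#' @param frac subsample fraction (default 2/3).
#' @param seed integer seed.
#' @return object of class \code{tree_distance}: \code{D} (cells x cells),
#'   \code{copresence}, \code{n_trees}, \code{frac}, \code{n_imputed}.
#' @export
bootstrap_mst_distances <- function(embedding, n_trees = 1000L, frac = 2/3,
                                    seed = 1L) {
  n <- nrow(embedding)
  if (n_trees < 1L) stop("n_trees must be at least 1")
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  m <- floor(frac * n)
  if (m < 2L) stop("frac * n_cells must be at least 2")
  set.seed(seed)
  coords <- as.matrix(embedding)
  dsum <- matrix(0, n, n)
  dcount <- matrix(0L, n, n)
  for (t in seq_len(n_trees)) {
    idx <- if (m == n) seq_len(n) else sample.int(n, m)
    .cpp_mst_accumulate(coords, idx - 1L, dsum, dcount)
  }
  D <- dsum / pmax(dcount, 1L)
  D[dcount == 0L] <- NA_real_
  diag(D) <- 0
  n_imputed <- 0L
  if (anyNA(D)) {
    obs <- which(!is.na(D) & upper.tri(D), arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(obs, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::E(g)$weight <- D[obs]
    sp <- igraph::distances(g)
    miss <- is.na(D)
    n_imputed <- sum(miss) / 2
    D[miss] <- sp[miss]
  }
  rownames(D) <- colnames(D) <- rownames(coords)
  structure(list(D = D, copresence = dcount, n_trees = as.integer(n_trees),
                 frac = frac, n_imputed = n_imputed),
            class = "tree_distance")
}

#' @export
print.tree_distance <- function(x, ...) {
  cat("tree_distance:", nrow(x$D), "cells,", x$n_trees,
      "trees, frac =", round(x$frac, 3),
      if (x$n_imputed > 0) paste0("(", x$n_imputed, " pairs imputed)"),
      "\n")
  invisible(x)
}

#' Classical multidimensional scaling of a tree distance
#'
#' Double-centered classical MDS (\code{stats::cmdscale}) of the averaged
#' tree distances; the default three dimensions give the embedding used to
#' fit the principal graph. Missing rank is zero-padded with a warning.
#'
#' @param treedist a \code{\link{bootstrap_mst_distances}} result (or a
#'   plain distance matrix).
#' @param dim target dimension (default 3).
#' @return cells x dim coordinate matrix with attribute \code{stress}
#'   (Kruskal stress-1 of the reproduced distances).
#' @export
mds_embed <- function(treedist, dim = 3L) {
  D <- if (inherits(treedist, "tree_distance")) treedist$D else treedist
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  fit <- stats::cmdscale(D, k = dim, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dim) {
    warning("distance rank below ", dim, "; zero-padding")
    pts <- cbind(pts, matrix(0, nrow(pts), dim - ncol(pts)))
  }
  dd <- as.matrix(stats::dist(pts))
  ut <- upper.tri(D)
  stress <- sqrt(sum((D[ut] - dd[ut])^2) / sum(D[ut]^2))
  attr(pts, "stress") <- stress
  rownames(pts) <- rownames(D)
  pts
}

# ---- elastic principal tree ------------------------------------------------

# quadratic solve of node positions given assignment; returns nodes matrix
.ep_solve <- function(points, assign_idx, nodes, edges, lambda, mu) {
  nn <- nrow(nodes)
  n <- nrow(points)
  A <- matrix(0, nn, nn)
  counts <- tabulate(assign_idx, nbins = nn)
  diag(A) <- counts / n
  B <- matrix(0, nn, ncol(points))
  for (k in seq_len(ncol(points)))
    B[, k] <- unname(tapply(points[, k],
                            factor(assign_idx, levels = seq_len(nn)),
                            sum, default = 0)) / n
  B[is.na(B)] <- 0
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1L]; v <- edges[e, 2L]
    A[u, u] <- A[u, u] + lambda; A[v, v] <- A[v, v] + lambda
    A[u, v] <- A[u, v] - lambda; A[v, u] <- A[v, u] - lambda
  }
  deg <- tabulate(c(edges), nbins = nn)
  adj <- lapply(seq_len(nn), function(j)
    c(edges[edges[, 1L] == j, 2L], edges[edges[, 2L] == j, 1L]))
  for (j in which(deg >= 2L)) {
    vvec <- rep(0, nn)
    vvec[j] <- 1
    vvec[adj[[j]]] <- vvec[adj[[j]]] - 1 / deg[j]
    A <- A + mu * tcrossprod(vvec)
  }
  diag(A) <- diag(A) + 1e-9
  solve(A, B)
}

.ep_assign <- function(points, nodes) {
  # nearest node per point via squared-distance expansion
  d2 <- outer(rowSums(points^2), rowSums(nodes^2), "+") -
    2 * points %*% t(nodes)
  max.col(-d2, ties.method = "first")
}

.ep_energy <- function(points, assign_idx, nodes, edges, lambda, mu) {
  approx <- sum((points - nodes[assign_idx, , drop = FALSE])^2) /
    nrow(points)
  el <- nodes[edges[, 1L], , drop = FALSE] -
    nodes[edges[, 2L], , drop = FALSE]
  stretch <- lambda * sum(el^2)
  deg <- tabulate(c(edges), nbins = nrow(nodes))
  bend <- 0
  for (j in which(deg >= 2L)) {
    nb <- c(edges[edges[, 1L] == j, 2L], edges[edges[, 2L] == j, 1L])
    bend <- bend + mu * sum((nodes[j, ] -
                               colMeans(nodes[nb, , drop = FALSE]))^2)
  }
  approx + stretch + bend
}

.ep_optimize <- function(points, nodes, edges, lambda, mu, n_iter = 5L) {
  for (i in seq_len(n_iter)) {
    a <- .ep_assign(points, nodes)
    nodes <- .ep_solve(points, a, nodes, edges, lambda, mu)
  }
  a <- .ep_assign(points, nodes)
  list(nodes = nodes, assign = a,
       energy = .ep_energy(points, a, nodes, edges, lambda, mu))
}

#' Fit an elastic principal tree
#'
#' Fits a skeleton of up to \code{max_nodes} nodes to the embedded cells by
#' minimizing the elastic energy: mean squared distance of each cell to its
#' nearest node, plus \code{lambda} times the summed squared edge lengths
#' (stretching) and \code{mu} times the squared deviation of each non-leaf
#' node from the mean of its neighbors (bending/branching stiffness).
#' Growth is by topological grafting: at each step the best of bisecting a
#' high-error edge or grafting a leaf at a high-error node is applied and
#' locally re-optimized, until the node budget is reached or the energy
#' gain vanishes. All energy terms are quadratic in length, so the
#' parameters are scale-free.
#'
#' @param points cells x dims coordinates (typically the 3-D MDS).
#' @param max_nodes node budget (default 100).
#' @param lambda edge-stretch penalty (default 0.01).
#' @param mu star-deviation penalty (default 0.1).
#' @param tol relative energy-gain tolerance for stopping (default 1e-4).
#' @param n_candidates how many high-error edges and nodes to try per step.
#' @return object of class \code{principal_tree}: \code{nodes} (coordinate
#'   matrix), \code{edges} (2-column node index matrix), \code{assignment}
#'   (per-cell nearest node), \code{energy}, \code{lambda}, \code{mu}.
#' @export
fit_principal_graph <- function(points, max_nodes = 100L, lambda = 0.01,
                                mu = 0.1, tol = 1e-4, n_candidates = 5L) {
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("non-finite coordinates")
  n <- nrow(points)
  if (n < max(10L, max_nodes / 2)) max_nodes <- max(2L, floor(n / 2))
  ctr <- colMeans(points)
  pc1 <- stats::prcomp(points, rank. = 1L)
  span <- stats::sd(pc1$x[, 1L])
  nodes <- rbind(ctr - pc1$rotation[, 1L] * span,
                 ctr + pc1$rotation[, 1L] * span)
  edges <- matrix(c(1L, 2L), nrow = 1L)
  cur <- .ep_optimize(points, nodes, edges, lambda, mu, n_iter = 10L)
  nodes <- cur$nodes

  while (nrow(nodes) < max_nodes) {
    node_err <- unname(tapply(
      rowSums((points - nodes[cur$assign, , drop = FALSE])^2),
      factor(cur$assign, levels = seq_len(nrow(nodes))), sum, default = 0))
    node_err[is.na(node_err)] <- 0
    # candidate bisections: edges with highest endpoint error
    edge_err <- node_err[edges[, 1L]] + node_err[edges[, 2L]]
    cand_edges <- order(edge_err, decreasing = TRUE)[
      seq_len(min(n_candidates, nrow(edges)))]
    # candidate grafts: highest-error nodes
    cand_nodes <- order(node_err, decreasing = TRUE)[
      seq_len(min(n_candidates, nrow(nodes)))]
    best <- NULL
    for (e in cand_edges) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      nn <- rbind(nodes, (nodes[u, ] + nodes[v, ]) / 2)
      mid <- nrow(nn)
      ne <- rbind(edges[-e, , drop = FALSE], c(u, mid), c(mid, v))
      trial <- .ep_optimize(points, nn, ne, lambda, mu)
      if (is.null(best) || trial$energy < best$energy)
        best <- c(trial, list(edges = ne))
    }
    for (j in cand_nodes) {
      pts_j <- points[cur$assign == j, , drop = FALSE]
      if (nrow(pts_j) == 0L) next
      # graft toward the worst-fit point assigned to j
      far <- pts_j[which.max(rowSums(sweep(pts_j, 2, nodes[j, ])^2)), ]
      nn <- rbind(nodes, (nodes[j, ] + far) / 2)
      ne <- rbind(edges, c(j, nrow(nn)))
      trial <- .ep_optimize(points, nn, ne, lambda, mu)
      if (is.null(best) || trial$energy < best$energy)
        best <- c(trial, list(edges = ne))
    }
    if (is.null(best)) break
    gain <- (cur$energy - best$energy) / cur$energy
    if (gain < tol && nrow(nodes) > 2L) break
    nodes <- best$nodes
    edges <- best$edges
    cur <- best
  }
  structure(list(nodes = nodes, edges = edges, assignment = cur$assign,
                 energy = cur$energy, lambda = lambda, mu = mu),
            class = "principal_tree")
}

#' @export
print.principal_tree <- function(x, ...) {
  deg <- tabulate(c(x$edges), nbins = nrow(x$nodes))
  cat("principal_tree:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      sum(deg == 1L), "tips,", sum(deg >= 3L), "branch points; energy",
      format(x$energy, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.principal_tree <- function(x, points = NULL, dims = c(1L, 2L), ...) {
  if (!is.null(points))
    graphics::plot(points[, dims], col = "grey70", pch = 16, cex = 0.5, ...)
  else
    graphics::plot(x$nodes[, dims], type = "n", ...)
  for (e in seq_len(nrow(x$edges)))
    graphics::segments(x$nodes[x$edges[e, 1L], dims[1L]],
                       x$nodes[x$edges[e, 1L], dims[2L]],
                       x$nodes[x$edges[e, 2L], dims[1L]],
                       x$nodes[x$edges[e, 2L], dims[2L]], lwd = 2)
  graphics::points(x$nodes[, dims], pch = 21, bg = "white")
  invisible(x)
}

# decompose the tree into maximal paths between topological nodes
# (degree != 2); returns list of integer node sequences
.tree_paths <- function(edges, n_nodes) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  deg <- igraph::degree(g)
  topo <- which(deg != 2L)
  if (length(topo) == 0L) topo <- 1L     # cycle-free guard; tree always has tips
  paths <- list()
  visited_edge <- matrix(FALSE, n_nodes, n_nodes)
  for (s in topo) {
    for (nb in igraph::neighbors(g, s)) {
      nb <- as.integer(nb)
      if (visited_edge[s, nb]) next
      path <- c(s, nb)
      visited_edge[s, nb] <- visited_edge[nb, s] <- TRUE
      while (deg[path[length(path)]] == 2L) {
        cur <- path[length(path)]
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)),
                       path[length(path) - 1L])
        visited_edge[cur, nxt] <- visited_edge[nxt, cur] <- TRUE
        path <- c(path, nxt)
      }
      paths[[length(paths) + 1L]] <- path
    }
  }
  paths
}

#' Prune spurious paths that start and end in the same cluster
#'
#' Decomposes the principal tree into maximal paths between topological
#' nodes, assigns each path endpoint the majority cluster of the cells
#' projected nearest to it, and removes leaf paths (spurs) whose two
#' endpoints carry the same dominant cluster, provided every cluster stays
#' represented and the graph stays connected. At least one path is always
#' retained.
#'
#' @param graph a \code{\link{fit_principal_graph}} result.
#' @param points the cell coordinates the tree was fit to.
#' @param cluster_labels per-cell cluster labels.
#' @return pruned \code{principal_tree} (cells reassigned), with attribute
#'   \code{pruned_paths} listing removed node sequences.
#' @export
prune_same_cluster_paths <- function(graph, points, cluster_labels) {
  stopifnot(length(cluster_labels) == nrow(points))
  nodes <- graph$nodes; edges <- graph$edges
  pruned <- list()
  repeat {
    assign_idx <- .ep_assign(as.matrix(points), nodes)
    paths <- .tree_paths(edges, nrow(nodes))
    if (length(paths) <= 1L) break
    # try short spurs first so a genuine long axis is never sacrificed
    path_len <- vapply(paths, function(p)
      sum(sqrt(rowSums((nodes[p[-length(p)], , drop = FALSE] -
                          nodes[p[-1L], , drop = FALSE])^2))), numeric(1))
    paths <- paths[order(path_len)]
    deg <- tabulate(c(edges), nbins = nrow(nodes))
    node_cluster <- function(j) {
      cl <- cluster_labels[assign_idx == j]
      if (length(cl) == 0L) return(NA_character_)
      names(sort(table(cl), decreasing = TRUE))[1L]
    }
    removed <- FALSE
    for (p in paths) {
      a <- p[1L]; b <- p[length(p)]
      # only spurs (a free end) can be removed from a tree without
      # disconnecting it
      if (deg[a] != 1L && deg[b] != 1L) next
      ca <- node_cluster(a); cb <- node_cluster(b)
      if (is.na(ca) || is.na(cb) || ca != cb) next
      drop_nodes <- if (deg[a] == 1L) p[-length(p)] else p[-1L]
      keep_nodes <- setdiff(seq_len(nrow(nodes)), drop_nodes)
      # every dominant cluster must stay dominant somewhere after removal
      before_cl <- stats::na.omit(vapply(seq_len(nrow(nodes)),
                                         node_cluster, character(1)))
      re_assign <- .ep_assign(as.matrix(points),
                              nodes[keep_nodes, , drop = FALSE])
      after_cl <- stats::na.omit(vapply(seq_along(keep_nodes),
                                        function(j) {
        cl <- cluster_labels[re_assign == j]
        if (length(cl) == 0L) NA_character_
        else names(sort(table(cl), decreasing = TRUE))[1L]
      }, character(1)))
      if (!all(unique(before_cl) %in% unique(after_cl))) next
      keep_edge <- !(edges[, 1L] %in% drop_nodes |
                       edges[, 2L] %in% drop_nodes)
      new_edges <- edges[keep_edge, , drop = FALSE]
      if (nrow(new_edges) == 0L) next
      remap <- match(seq_len(nrow(nodes)), keep_nodes)
      new_edges[] <- remap[new_edges]
      g2 <- igraph::graph_from_edgelist(new_edges, directed = FALSE)
      g2 <- igraph::add_vertices(g2, max(0L, length(keep_nodes) -
                                           igraph::vcount(g2)))
      if (igraph::components(g2)$no > 1L) { next }
      pruned[[length(pruned) + 1L]] <- p
      nodes <- nodes[keep_nodes, , drop = FALSE]
      edges <- new_edges
      removed <- TRUE
      break
    }
    if (!removed) break
  }
  out <- graph
  out$nodes <- nodes
  out$edges <- edges
  out$assignment <- .ep_assign(as.matrix(points), nodes)
  attr(out, "pruned_paths") <- pruned
  out
}

#' Project cells on the principal tree and order them from a root
#'
#' Orthogonally projects each cell onto its nearest tree edge (projection
#' parameter clamped to the segment) and defines the pseudo-order as the
#' along-graph distance from the root to the projection, rescaled to
#' \[0, 1\]. The branch label is the maximal-path id of the cell's edge.
#'
#' @param graph a \code{\link{fit_principal_graph}} (possibly pruned).
#' @param points cells x dims coordinates.
#' @param root root node index (e.g. from \code{\link{pick_root}}).
#' @return data.frame: cell (rowname of points), pseudo_order in \[0,1\],
#'   branch, edge, t (position along the edge), dist_to_tree.
#' @export
project_and_order <- function(graph, points, root = 1L) {
  nodes <- graph$nodes; edges <- graph$edges
  if (root < 1L || root > nrow(nodes)) stop("root not in graph")
  pts <- as.matrix(points)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n); best_e <- integer(n); best_t <- numeric(n)
  for (e in seq_len(nrow(edges))) {
    u <- nodes[edges[e, 1L], ]; v <- nodes[edges[e, 2L], ]
    seg <- v - u
    len2 <- sum(seg^2)
    tt <- if (len2 == 0) rep(0, n)
          else pmin(pmax((sweep(pts, 2, u) %*% seg) / len2, 0), 1)
    proj <- outer(as.numeric(tt), seg) + rep(u, each = n)
    d2 <- rowSums((pts - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; best_e[upd] <- e; best_t[upd] <- tt[upd]
  }
  # node-level distances from root along the tree
  elen <- sqrt(rowSums((nodes[edges[, 1L], , drop = FALSE] -
                          nodes[edges[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(nodes) - igraph::vcount(g)))
  igraph::E(g)$weight <- pmax(elen, 1e-12)
  nd <- as.numeric(igraph::distances(g, v = root))
  ord <- nd[edges[best_e, 1L]] + best_t * elen[best_e]
  # when the edge points "toward" the root, measure from the nearer end
  alt <- nd[edges[best_e, 2L]] + (1 - best_t) * elen[best_e]
  ord <- pmin(ord, alt)
  rng <- range(ord)
  scaled <- if (diff(rng) > 0) (ord - rng[1L]) / diff(rng) else ord * 0
  # branch id: path membership of the edge
  paths <- .tree_paths(edges, nrow(nodes))
  edge_path <- integer(nrow(edges))
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    for (s in seq_len(length(p) - 1L)) {
      hit <- which((edges[, 1L] == p[s] & edges[, 2L] == p[s + 1L]) |
                     (edges[, 2L] == p[s] & edges[, 1L] == p[s + 1L]))
      edge_path[hit] <- pi
    }
  }
  data.frame(cell = rownames(pts) %||% as.character(seq_len(n)),
             pseudo_order = as.numeric(scaled), branch = edge_path[best_e],
             edge = best_e, t = as.numeric(best_t),
             dist_to_tree = sqrt(best_d2), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick the deep-quiescence root node
#'
#' Chooses the tree node whose projected cells have the highest mean glial
#' score and lowest ribosomal score (their difference), i.e. the
#' deep-quiescence end of the axis.
#'
#' @param graph a \code{principal_tree}.
#' @param points cell coordinates.
#' @param glial_score,ribo_score per-cell scores.
#' @return node index.
#' @export
pick_root <- function(graph, points, glial_score, ribo_score) {
  assign_idx <- .ep_assign(as.matrix(points), graph$nodes)
  crit <- glial_score - ribo_score
  deg <- tabulate(c(graph$edges), nbins = nrow(graph$nodes))
  tips <- which(deg == 1L)
  means <- vapply(tips, function(j) {
    v <- crit[assign_idx == j]
    if (length(v) == 0L) -Inf else mean(v)
  }, numeric(1))
  tips[which.max(means)]
}

#' Genes associated with pseudo-order
#'
#' Spearman correlation of each gene with the pseudo-order, with BH-FDR;
#' the signed correlation doubles as a ranking statistic compatible with
#' \code{\link{gsea_preranked}}. Constant genes get rho 0 and p 1.
#'
#' @param normalized genes x cells normalized expression.
#' @param pseudo_order per-cell pseudo-order.
#' @return data.frame: gene, rho, p, q, ordered by decreasing |rho|.
#' @export
depth_associated_genes <- function(normalized, pseudo_order) {
  stopifnot(ncol(normalized) == length(pseudo_order))
  n <- length(pseudo_order)
  ro <- rank(pseudo_order)
  x <- as.matrix(normalized)
  rx <- t(apply(x, 1, rank))
  ro_c <- ro - mean(ro)
  rx_c <- rx - rowMeans(rx)
  denom <- sqrt(rowSums(rx_c^2) * sum(ro_c^2))
  rho <- as.numeric(rx_c %*% ro_c) / ifelse(denom > 0, denom, 1)
  rho[denom == 0] <- 0
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[denom == 0] <- 1
  out <- data.frame(gene = rownames(normalized), rho = rho, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(abs(out$rho), decreasing = TRUE), ]
}
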