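test_that("diffusion map unrolls a noisy 1-D curve", {
  set.seed(51)
  n <- 200L
  t <- sort(runif(n))
  # ten "genes" varying smoothly along the curve parameter, plus noise
  x <- rbind(sin(pi * t), cos(pi * t), t, t^2, sqrt(t),
             1 - t, sin(2 * t), exp(-t), t^3, cos(2 * t))
  x <- x + matrix(rnorm(10 * n, 0, 0.05), nrow = 10)
  rownames(x) <- sprintf("g%d", 1:10)
  colnames(x) <- sprintf("c%d", 1:n)
  dm <- diffusion_map(x, rownames(x), n_components = 3L)
  expect_gte(abs(spearman(dm[, 1], t)), 0.9)
  # duplicated cell gets an identical embedding row
  x2 <- cbind(x, dup = x[, 1])
  dm2 <- diffusion_map(x2, rownames(x2), n_components = 2L)
  expect_equal(unname(dm2[1, ]), unname(dm2[n + 1L, ]), tolerance = 1e-8)
  expect_error(diffusion_map(x, rownames(x), n_components = 0L),
               "at least 1")
})

test_that("single full-data tree matches the exhaustive spanning-tree oracle", {
  set.seed(52)
  pts <- matrix(rnorm(7 * 3), nrow = 7)
  rownames(pts) <- sprintf("c%d", 1:7)
  td <- bootstrap_mst_distances(pts, n_trees = 1L, frac = 1, seed = 1L)
  oracle <- oracle_mst_paths(pts)
  expect_equal(unname(td$D), oracle$D, tolerance = 1e-12)
})

test_that("tree distances are additive along collinear points", {
  pts <- cbind(c(0, 1, 3), 0)
  rownames(pts) <- c("A", "B", "C")
  td <- bootstrap_mst_distances(pts, n_trees = 1L, frac = 1, seed = 1L)
  expect_equal(td$D["A", "C"], td$D["A", "B"] + td$D["B", "C"],
               tolerance = 1e-12)
  expect_true(isSymmetric(td$D))
  expect_true(all(diag(td$D) == 0))
  expect_error(bootstrap_mst_distances(pts, n_trees = 0L), "n_trees")
  expect_error(bootstrap_mst_distances(pts, frac = 0.1), "at least 2")
})

test_that("bootstrapped tree distance tracks a planted linear manifold", {
  set.seed(53)
  n <- 150L
  depth <- runif(n)
  pts <- cbind(depth * 10, rnorm(n, 0, 0.3), rnorm(n, 0, 0.3))
  rownames(pts) <- sprintf("c%d", 1:n)
  td <- bootstrap_mst_distances(pts, n_trees = 200L, frac = 2 / 3,
                                seed = 2L)
  endpoint <- which.min(depth)
  expect_gte(spearman(td$D[endpoint, ], depth), 0.9)
  # copresence bookkeeping: every pair seen roughly frac^2 of the time
  off <- td$copresence[upper.tri(td$copresence)]
  expect_gt(min(off), 0)
  expect_lt(abs(mean(off) / 200 - (2 / 3)^2 * (1 + 1 / n)), 0.05)
})

test_that("classical MDS reproduces Euclidean configurations exactly", {
  set.seed(54)
  conf <- matrix(rnorm(25 * 3), nrow = 25)
  D <- as.matrix(dist(conf))
  rec <- mds_embed(D, dim = 3L)
  # Procrustes: align and compare
  pro <- vegan::procrustes(conf, rec)
  expect_lt(sqrt(mean(residuals(pro)^2)), 1e-6)
  # 1-D data: ordering preserved
  line <- matrix(sort(runif(20)) * 5)
  rec1 <- mds_embed(as.matrix(dist(line)), dim = 1L)
  expect_equal(abs(spearman(rec1[, 1], line[, 1])), 1)
})

test_that("principal tree fits a path on line data and a Y on Y data", {
  set.seed(55)
  n <- 300L
  t <- runif(n)
  line <- cbind(t * 10, rnorm(n, 0, 0.15), rnorm(n, 0, 0.15))
  pg <- fit_principal_graph(line, max_nodes = 20L)
  deg <- tabulate(c(pg$edges), nrow(pg$nodes))
  expect_equal(sum(deg == 1L), 2L)
  expect_equal(sum(deg >= 3L), 0L)
  ordd <- project_and_order(pg, line, root = which(deg == 1L)[1])
  expect_gte(abs(spearman(ordd$pseudo_order, t)), 0.99)

  m <- 150L
  arm1 <- cbind(seq(0, 5, length.out = m), 0, 0)
  arm2 <- cbind(5 + seq(0, 4, length.out = m) * 0.7,
                seq(0, 4, length.out = m), 0)
  arm3 <- cbind(5 + seq(0, 4, length.out = m) * 0.7,
                -seq(0, 4, length.out = m), 0)
  Y <- rbind(arm1, arm2, arm3) + matrix(rnorm(9 * m, 0, 0.15), ncol = 3)
  pgy <- fit_principal_graph(Y, max_nodes = 25L)
  degy <- tabulate(c(pgy$edges), nrow(pgy$nodes))
  expect_equal(sum(degy == 3L), 1L)
  expect_equal(sum(degy > 3L), 0L)
  expect_equal(sum(degy == 1L), 3L)
  expect_error(fit_principal_graph(line * NA), "non-finite")
})

test_that("a two-node tree aligns with the first principal component", {
  set.seed(56)
  n <- 200L
  line <- cbind(runif(n) * 10, rnorm(n, 0, 0.2), rnorm(n, 0, 0.2))
  pg <- fit_principal_graph(line, max_nodes = 2L)
  expect_equal(nrow(pg$edges), 1L)
  v <- pg$nodes[2, ] - pg$nodes[1, ]
  pc1 <- prcomp(line)$rotation[, 1]
  cosang <- abs(sum(v * pc1)) / sqrt(sum(v^2))
  expect_gt(cosang, 0.99)
})

test_that("pruning removes same-cluster spurs and nothing else", {
  # hand-built tree: a 4-node backbone with a 2-node spur off node 2
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0),
                 c(1, 0.6, 0), c(1, 1.2, 0))
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(2L, 5L), c(5L, 6L))
  pg <- structure(list(nodes = nodes, edges = edges,
                       assignment = NULL, energy = 0,
                       lambda = 0.01, mu = 0.1),
                  class = "principal_tree")
  set.seed(57)
  pts <- rbind(
    cbind(runif(60, 0, 0.5), rnorm(60, 0, 0.05), 0),  # cluster a
    cbind(runif(60, 0.5, 2.5), rnorm(60, 0, 0.05), 0),# cluster b
    cbind(runif(60, 2.5, 3), rnorm(60, 0, 0.05), 0),  # cluster c
    cbind(rnorm(30, 1, 0.05), runif(30, 0.3, 1.2), 0))# spur, in cluster b
  cl <- c(rep("a", 60), rep("b", 60), rep("c", 60), rep("b", 30))
  pruned <- prune_same_cluster_paths(pg, pts, cl)
  expect_equal(nrow(pruned$nodes), 4L)
  expect_equal(nrow(pruned$edges), 3L)
  # ordered clusters along a clean path: nothing pruned
  clean <- structure(list(nodes = nodes[1:4, ], edges = edges[1:3, ],
                          assignment = NULL, energy = 0,
                          lambda = 0.01, mu = 0.1),
                     class = "principal_tree")
  same <- prune_same_cluster_paths(clean, pts[1:180, ], cl[1:180])
  expect_equal(nrow(same$nodes), 4L)
  # single-cluster guard: pruning terminates with at most one path
  allone <- prune_same_cluster_paths(pg, pts, rep("z", nrow(pts)))
  g <- igraph::graph_from_edgelist(allone$edges, directed = FALSE)
  expect_lte(sum(igraph::degree(g) >= 3L), 0L)
})

test_that("projection orders cells and reverses cleanly with the root", {
  set.seed(58)
  n <- 250L
  t <- runif(n)
  line <- cbind(t * 8, rnorm(n, 0, 0.1), rnorm(n, 0, 0.1))
  pg <- fit_principal_graph(line, max_nodes = 15L)
  deg <- tabulate(c(pg$edges), nrow(pg$nodes))
  tips <- which(deg == 1L)
  o1 <- project_and_order(pg, line, root = tips[1])
  o2 <- project_and_order(pg, line, root = tips[2])
  expect_equal(spearman(o1$pseudo_order, o2$pseudo_order), -1,
               tolerance = 1e-9)
  expect_true(all(o1$pseudo_order >= 0 & o1$pseudo_order <= 1))
  # a point exactly at a node orders at that node's scaled root distance
  probe <- rbind(pg$nodes[tips[2], ])
  po <- project_and_order(pg, rbind(line, probe), root = tips[1])
  expect_equal(po$pseudo_order[n + 1L], max(po$pseudo_order),
               tolerance = 1e-9)
  expect_error(project_and_order(pg, line, root = 999L), "root")
})

test_that("depth-associated genes are recovered with controlled FDR", {
  sim <- traj_fixture()
  norm <- normalize_counts(sim$counts)
  planted <- c(traj_deep_genes(sim$truth), traj_shallow_genes(sim$truth))
  dg <- depth_associated_genes(norm, sim$truth$depth)
  hits <- dg$gene[dg$q < 0.05]
  expect_gte(mean(planted %in% hits), 0.9)
  # permuted pseudo-order: false-positive rate within 1.5x nominal FDR
  set.seed(59)
  dg0 <- depth_associated_genes(norm, sample(sim$truth$depth))
  expect_lte(mean(dg0$q < 0.05), 1.5 * 0.05)
  # rank invariance under monotone transforms
  dg2 <- depth_associated_genes(norm, sim$truth$depth^3)
  expect_equal(dg$rho[order(dg$gene)], dg2$rho[order(dg2$gene)],
               tolerance = 1e-12)
})

test_that("pseudo-ordering is stable in the number of trees", {
  sim <- traj_fixture()
  norm <- normalize_counts(sim$counts)
  vg <- select_variable_genes(sim$counts, n_top = 200L)
  dm <- diffusion_map(norm, vg, n_components = 5L)
  run_order <- function(nt) {
    td <- bootstrap_mst_distances(dm, n_trees = nt, frac = 2 / 3,
                                  seed = 6L)
    emb <- mds_embed(td, dim = 3L)
    pg <- fit_principal_graph(emb, max_nodes = 50L)
    pg <- prune_same_cluster_paths(pg, emb, rep(1L, nrow(emb)))
    deg <- tabulate(c(pg$edges), nrow(pg$nodes))
    project_and_order(pg, emb, root = which(deg == 1L)[1])$pseudo_order
  }
  o1 <- run_order(250L)
  o2 <- run_order(500L)
  expect_gte(abs(spearman(o1, o2)), 0.99)
})
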