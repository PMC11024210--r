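test_that("generator handles the empty case and rejects bad configs", {
  out <- generate_counts(sim_config(n_cells = 0L, n_genes = 100L,
                                    n_clusters = 2L,
                                    n_markers_per_cluster = 5L))
  expect_equal(ncol(out$counts), 0L)
  expect_equal(length(out$truth$cell), 0L)
  expect_error(sim_config(marker_logfc = NaN), "non-finite")
  expect_error(sim_config(lowq_fraction = 1.2), "fractions")
  expect_error(sim_config(doublet_rate = 1), "doublet_rate")
  expect_error(sim_config(n_genes = 100, n_clusters = 10,
                          n_markers_per_cluster = 20), "exceeds")
})

test_that("same seed gives bit-identical output", {
  cfg <- sim_config(n_cells = 50L, n_genes = 120L, n_clusters = 2L,
                    n_markers_per_cluster = 5L, lowq_fraction = 0.2,
                    seed = 99L)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$truth$cluster, b$truth$cluster)
})

test_that("zero marker effect leaves marker means equal across clusters", {
  cfg <- sim_config(n_cells = 600L, n_genes = 400L, n_clusters = 3L,
                    n_markers_per_cluster = 20L, marker_logfc = 0,
                    seed = 13L)
  sim <- generate_counts(cfg)
  norm <- normalize_counts(sim$counts)
  # for each cluster's markers, in-cluster vs out-of-cluster mean are equal
  # within sampling error (standardized difference small)
  for (k in 1:3) {
    mk <- sim$truth$marker_sets[[k]]
    inm <- Matrix::colMeans(norm[mk, sim$truth$cluster == k, drop = FALSE])
    outm <- Matrix::colMeans(norm[mk, sim$truth$cluster != k, drop = FALSE])
    z <- (mean(inm) - mean(outm)) /
      sqrt(var(inm) / length(inm) + var(outm) / length(outm))
    expect_lt(abs(z), 4)
  }
})

test_that("low-quality mode yields a bimodal detected-gene histogram", {
  cfg <- sim_config(n_cells = 1000L, n_genes = 2000L, lowq_fraction = 0.1,
                    seed = 42L)
  sim <- generate_counts(cfg)
  ngene <- Matrix::colSums(sim$counts > 0)
  fit <- mclust::Mclust(log(ngene), G = 2L, verbose = FALSE)
  modes <- sort(exp(fit$parameters$mean))
  planted <- c(median(ngene[sim$truth$is_lowq]),
               median(ngene[!sim$truth$is_lowq]))
  expect_lt(abs(modes[1] - planted[1]) / planted[1], 0.15)
  expect_lt(abs(modes[2] - planted[2]) / planted[2], 0.15)
  # good-cell mode sits near the 900 detected-gene peak the QC emulates
  expect_gt(planted[2], 700)
  expect_lt(planted[2], 1100)
})

test_that("doublet injection conserves parental column sums", {
  sim <- small_fixture()
  same <- inject_doublets(sim$counts, sim$truth, rate = 0, seed = 1L)
  expect_identical(ncol(same$counts), ncol(sim$counts))
  inj <- inject_doublets(sim$counts, sim$truth, rate = 0.05, seed = 2L)
  n_doub <- round(0.05 * ncol(sim$counts))
  expect_equal(ncol(inj$counts), ncol(sim$counts) + n_doub)
  expect_equal(sum(inj$truth$is_doublet), n_doub)
  cs <- Matrix::colSums(sim$counts)
  for (i in seq_len(n_doub)) {
    par <- inj$truth$doublet_parents[i, ]
    expect_identical(
      unname(Matrix::colSums(inj$counts)[ncol(sim$counts) + i]),
      unname(cs[par[1]] + cs[par[2]]))
  }
  expect_error(inject_doublets(sim$counts, sim$truth, rate = 1), "rate")
})

test_that("doublets score high for both parent clusters", {
  sim <- small_fixture()
  inj <- inject_doublets(sim$counts, sim$truth, rate = 0.05, seed = 3L)
  norm <- normalize_counts(inj$counts)
  truth <- inj$truth
  # marker score per cluster = mean normalized expression of its markers
  msc <- vapply(sim$truth$marker_sets, function(g)
    Matrix::colMeans(norm[g, , drop = FALSE]), numeric(ncol(norm)))
  singlets <- seq_len(ncol(sim$counts))
  for (i in which(truth$is_doublet)[1:5]) {
    par_cl <- sim$truth$cluster[truth$doublet_parents[
      i - ncol(sim$counts), ]]
    for (k in unique(par_cl)) {
      nonparent <- msc[singlets[!(sim$truth$cluster %in% par_cl)], k]
      expect_gt(msc[i, k], quantile(nonparent, 0.5))
    }
  }
})

test_that("trajectory counts track the planted depth", {
  sim <- traj_fixture()
  norm <- normalize_counts(sim$counts)
  deep <- traj_deep_genes(sim$truth)
  shal <- traj_shallow_genes(sim$truth)
  expect_gte(spearman(sim$truth$depth, Matrix::colMeans(norm[deep, ])), 0.8)
  expect_lte(spearman(sim$truth$depth, Matrix::colMeans(norm[shal, ])),
             -0.8)
  expect_error(generate_trajectory_counts(
    sim_config(trajectory = TRUE, depth_module_size = 0L)), "module_size")
  expect_error(generate_trajectory_counts(sim_config()), "not enabled")
})

test_that("Y-branch terminal states separate by branch-module means", {
  sim <- generate_trajectory_counts(sim_config(
    n_cells = 600L, n_genes = 600L, trajectory = TRUE,
    depth_module_size = 30L, branch = TRUE, branch_module_size = 30L,
    depth_logfc = log(2), nb_dispersion = 10, libsize_mean = 8000,
    libsize_dispersion = 0.15, seed = 17L))
  norm <- normalize_counts(sim$counts)
  late <- sim$truth$depth > 0.8
  m1 <- Matrix::colMeans(norm[sim$truth$branch_sets[[1]], ])
  m2 <- Matrix::colMeans(norm[sim$truth$branch_sets[[2]], ])
  b1 <- late & sim$truth$branch == 1L
  b2 <- late & sim$truth$branch == 2L
  # each late branch is closer to its own module centroid
  expect_gt(mean(m1[b1]) - mean(m1[b2]),
            2 * sqrt(var(m1[b1]) / sum(b1) + var(m1[b2]) / sum(b2)))
  expect_gt(mean(m2[b2]) - mean(m2[b1]),
            2 * sqrt(var(m2[b2]) / sum(b2) + var(m2[b1]) / sum(b1)))
})

test_that("clone table matches the requested composition law", {
  all_rg <- generate_clone_table(4L, 5L, p_rg_only = 1, chase_days = 10L)
  expect_true(all(all_rg$composition == "RG_only"))
  big <- generate_clone_table(50L, 10L, p_rg_only = 0.43,
                              chase_days = 507L, seed = 8L)
  p_hat <- mean(big$composition == "RG_only")
  ci <- qbinom(c(0.005, 0.995), nrow(big), 0.43) / nrow(big)
  expect_gte(p_hat, ci[1])
  expect_lte(p_hat, ci[2])
  ranged <- generate_clone_table(9L, 4:11, p_rg_only = 0.5,
                                 chase_days = c(6L, 507L), seed = 9L)
  per_hemi <- table(ranged$hemisphere_id)
  expect_true(all(per_hemi >= 4 & per_hemi <= 11))
  expect_error(generate_clone_table(4L, 5L, 0.5, integer(0)), "chase_days")
})

test_that("ortholog table counts and mapping invariants hold", {
  bij <- generate_ortholog_table(50L, 0, 0)
  zf <- bij$gene_id[bij$species == "zf"]
  mm <- bij$gene_id[bij$species == "mm"]
  expect_equal(length(zf), length(mm))
  expect_equal(length(unique(bij$group_id)), 50L)
  multi <- generate_ortholog_table(100L, frac_one2many = 0.3, seed = 4L)
  n_two <- sum(table(multi$group_id[multi$species == "zf"]) == 2L)
  expect_identical(n_two, 30L)
  # every gene maps to exactly one group
  expect_false(anyDuplicated(multi[, c("species", "gene_id")]) > 0)
  expect_error(generate_ortholog_table(10L, 0.8, 0.4), "fractions")
})
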