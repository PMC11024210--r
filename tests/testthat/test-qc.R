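test_that("per-cell QC metrics are exact on a hand-built matrix", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 2), j = c(2, 2, 3),
                            x = c(1, 3, 5), dims = c(2, 3))
  rownames(m) <- c("mt-1", "geneA")
  colnames(m) <- c("empty", "mixed", "pure")
  qc <- compute_cell_qc(m)
  expect_equal(qc$nUMI, c(0, 4, 5))
  expect_equal(qc$nGene, c(0L, 2L, 1L))
  expect_equal(qc$percent.mito, c(0, 25, 0))
  expect_error(compute_cell_qc(m[integer(0), ]), "no genes")
})

test_that("low-quality cells carry elevated mitochondrial load", {
  sim <- generate_counts(sim_config(n_cells = 500L, n_genes = 1000L,
                                    lowq_fraction = 0.15, seed = 12L))
  qc <- compute_cell_qc(sim$counts)
  expect_gt(mean(qc$percent.mito[sim$truth$is_lowq]),
            mean(qc$percent.mito[!sim$truth$is_lowq]))
})

test_that("loess complexity filter keeps on-trend cells and flags outliers", {
  set.seed(3)
  numi <- round(runif(500, 1000, 6000))
  qc <- data.frame(cell_id = sprintf("c%d", 1:501),
                   nUMI = c(numi, 3000),
                   nGene = as.integer(c(round(numi * 0.3), 4500)))
  res <- loess_complexity_filter(qc, qc_thresholds())
  expect_true(all(res$keep[1:500]))
  # on-trend residuals are tiny relative to the outlier's displacement
  expect_lt(max(abs(res$residual[1:500])), 0.05 * abs(res$residual[501]))
  expect_false(res$keep[501])             # 5x-over-trend planted outlier
  # oracle: a global linear fit flags the same cell
  z <- abs(resid(lm(nGene ~ nUMI, qc)))
  expect_equal(unname(which.max(z)), 501L)
  loose <- loess_complexity_filter(qc, qc_thresholds(sd_cut = 1e6))
  expect_true(all(loose$keep))
  qc$nUMI <- 1000
  expect_error(loess_complexity_filter(qc, qc_thresholds()), "degenerate")
})

test_that("threshold filtering uses strict boundaries in the stated order", {
  set.seed(4)
  m <- matrix(rpois(300 * 60, 3), nrow = 300)
  rownames(m) <- c(sprintf("mt-%d", 1:6), sprintf("g%d", 1:294))
  colnames(m) <- sprintf("c%d", 1:60)
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  qc <- compute_cell_qc(m)
  # force two boundary cells: nGene 199 (drop) and 200 (keep)
  qc$nGene[1] <- 199L; qc$nGene[2] <- 200L
  filt <- threshold_filter(m, qc, qc_thresholds(gene_min_cells = 0L))
  expect_false("c1" %in% colnames(filt))
  expect_true("c2" %in% colnames(filt))
  # gene boundary: expressed in exactly 10 surviving cells -> kept; 9 -> dropped
  m2 <- m; m2[10, ] <- 0; m2[10, 1:10] <- 1
  m3 <- m; m3[10, ] <- 0; m3[10, 1:9] <- 1
  qc2 <- compute_cell_qc(m2); qc3 <- compute_cell_qc(m3)
  thr <- qc_thresholds(min_genes = 0L, max_mito_pct = 100)
  expect_true(rownames(m)[10] %in% rownames(threshold_filter(m2, qc2, thr)))
  expect_false(rownames(m)[10] %in% rownames(threshold_filter(m3, qc3, thr)))
  # all-permissive thresholds are the identity
  ident <- threshold_filter(m, compute_cell_qc(m),
                            qc_thresholds(min_genes = 0L,
                                          max_mito_pct = 100,
                                          gene_min_cells = 0L))
  expect_identical(dim(ident), dim(m))
  expect_error(threshold_filter(m, compute_cell_qc(m),
                                qc_thresholds(min_genes = 10000L)),
               "all cells")
})

test_that("threshold filtering is idempotent", {
  sim <- generate_counts(sim_config(n_cells = 400L, n_genes = 1200L,
                                    lowq_fraction = 0.1, seed = 15L))
  qc <- compute_cell_qc(sim$counts)
  once <- threshold_filter(sim$counts, qc, qc_thresholds())
  twice <- threshold_filter(once, compute_cell_qc(once), qc_thresholds())
  expect_identical(dim(once), dim(twice))
})

test_that("variable-gene selection recovers planted markers", {
  sim <- std_fixture()
  n_markers <- length(unlist(sim$truth$marker_sets))
  vg <- select_variable_genes(sim$counts, n_top = 2L * n_markers)
  recall <- mean(unlist(sim$truth$marker_sets) %in% vg)
  expect_gte(recall, 0.8)
  expect_length(select_variable_genes(sim$counts, n_top = 0L), 0L)
  const <- Matrix::Matrix(1, 5, 10, sparse = TRUE)
  rownames(const) <- sprintf("g%d", 1:5)
  expect_length(select_variable_genes(const, n_top = 3L), 0L)
})

test_that("PC selection finds structure and rejects noise", {
  # pure Gaussian noise: no component should survive the permutation test
  set.seed(6)
  noise <- matrix(rnorm(200 * 300), nrow = 200)
  rownames(noise) <- sprintf("g%d", 1:200)
  colnames(noise) <- sprintf("c%d", 1:300)
  n_sig <- select_pcs(noise, rownames(noise), n_max = 15L,
                      jackstraw_reps = 40L, seed = 2L)
  expect_lte(n_sig, 1L)   # within type-I tolerance of the permutation test
  sim <- small_fixture()  # 3 planted clusters
  norm <- normalize_counts(sim$counts)
  vg <- select_variable_genes(sim$counts, n_top = 300L)
  n_str <- select_pcs(norm, vg, n_max = 15L, jackstraw_reps = 40L,
                      seed = 2L)
  expect_gte(n_str, 2L)   # at least K - 1 structural components
  expect_equal(select_pcs(norm, vg, n_max = 15L, var_threshold = 1,
                          jackstraw_reps = 10L, seed = 2L), 0L,
               ignore_attr = TRUE)
  expect_error(select_pcs(norm, character(0)), "empty")
})

test_that("loess filter is approximately scale-equivariant", {
  sim <- generate_counts(sim_config(n_cells = 500L, n_genes = 1000L,
                                    lowq_fraction = 0.1, seed = 33L))
  qc1 <- compute_cell_qc(sim$counts)
  qc10 <- compute_cell_qc(sim$counts * 10)
  f1 <- loess_complexity_filter(qc1, qc_thresholds())
  f10 <- loess_complexity_filter(qc10, qc_thresholds())
  expect_lt(mean(f1$keep != f10$keep), 0.01)
})
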