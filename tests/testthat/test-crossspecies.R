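two_species_fixture <- function() memo("two_species", function() {
  tab <- generate_ortholog_table(200L, frac_one2many = 0.25,
                                 frac_missing = 0.1, seed = 61L)
  zf_genes <- tab$gene_id[tab$species == "zf"]
  mm_genes <- tab$gene_id[tab$species == "mm"]
  mk <- function(genes, n_cells, n_clusters, seed) {
    cfg <- sim_config(n_cells = n_cells, n_genes = length(genes),
                      n_clusters = n_clusters, n_markers_per_cluster = 25L,
                      marker_logfc = 2, seed = seed)
    sim <- generate_counts(cfg)
    # rename simulated genes into the species' gene ids, carrying the
    # marker sets through the renaming
    orig <- rownames(sim$counts)
    sim$truth$marker_sets <- lapply(sim$truth$marker_sets, function(g)
      genes[match(g, orig)])
    rownames(sim$counts) <- genes
    sim
  }
  # order genes by group so marker blocks hit the same groups per species
  tab_zf <- tab[tab$species == "zf", ]
  tab_mm <- tab[tab$species == "mm", ]
  list(table = tab,
       zf = mk(tab_zf$gene_id, 250L, 4L, 62L),
       mm = mk(tab_mm$gene_id, 250L, 4L, 63L))
})

test_that("group collapse conserves counts and sums paralogs", {
  fx <- two_species_fixture()
  zc <- collapse_to_groups(fx$zf$counts, fx$table, "zf")
  total_in <- sum(fx$zf$counts)
  dropped <- attr(zc, "dropped_genes")
  expect_equal(sum(zc) + sum(fx$zf$counts[dropped, , drop = FALSE]),
               total_in)
  # a known two-paralog group sums both genes per cell
  audit <- attr(zc, "audit")
  multi <- audit$group_id[audit$n_paralogs == 2L][1]
  paralogs <- audit$gene_id[audit$group_id == multi]
  expect_length(paralogs, 2L)
  expect_equal(as.numeric(zc[multi, ]),
               as.numeric(Matrix::colSums(fx$zf$counts[paralogs, ])))
  expect_error(collapse_to_groups(fx$zf$counts, fx$table, "nope"),
               "not in ortholog table")
})

test_that("one-to-one tables collapse to a pure relabeling", {
  tab <- generate_ortholog_table(40L, 0, 0)
  set.seed(64)
  m <- matrix(rpois(40 * 12, 3), nrow = 40)
  rownames(m) <- tab$gene_id[tab$species == "zf"]
  colnames(m) <- sprintf("c%d", 1:12)
  m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  zc <- collapse_to_groups(m, tab, "zf")
  expect_equal(dim(zc), dim(m))
  expect_equal(unname(Matrix::colSums(zc)), unname(Matrix::colSums(m)))
  expect_equal(sort(unname(Matrix::rowSums(zc))),
               sort(unname(Matrix::rowSums(m))))
})

test_that("a dataset maps onto itself with a diagonal homology", {
  fx <- two_species_fixture()
  cl <- fx$zf$truth$cluster
  groups <- collapse_to_groups(fx$zf$counts, fx$table, "zf")
  hm <- neighbor_voting_auroc(groups, cl, groups, cl)
  expect_true(all(diag(hm) >= 0.95))
  expect_true(all(hm >= 0 & hm <= 1))
  # off-diagonal entries are markedly weaker
  off <- hm[upper.tri(hm)]
  expect_lt(max(off), min(diag(hm)))
})

test_that("shuffled labels drive homology to chance", {
  fx <- two_species_fixture()
  cl <- fx$zf$truth$cluster
  groups <- collapse_to_groups(fx$zf$counts, fx$table, "zf")
  set.seed(65)
  means <- vapply(1:10, function(i)
    mean(neighbor_voting_auroc(groups, cl, groups, sample(cl))),
    numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.05)
})

test_that("degenerate single-cluster homology is 1 by contract", {
  fx <- two_species_fixture()
  groups <- collapse_to_groups(fx$zf$counts, fx$table, "zf")
  one <- rep(1L, ncol(groups))
  hm <- neighbor_voting_auroc(groups, one, groups, one)
  expect_equal(dim(hm), c(1L, 1L))
  expect_equal(hm[1, 1], 1)
})

test_that("homology is invariant to cell order", {
  fx <- two_species_fixture()
  cl <- fx$zf$truth$cluster
  groups <- collapse_to_groups(fx$zf$counts, fx$table, "zf")
  set.seed(66)
  perm <- sample(ncol(groups))
  h1 <- neighbor_voting_auroc(groups, cl, groups, cl)
  h2 <- neighbor_voting_auroc(groups[, perm], cl[perm], groups, cl)
  expect_equal(h1, h2, tolerance = 1e-9)
})

test_that("gene-set co-expression calls distinguish planted patterns", {
  fx <- two_species_fixture()
  sim <- fx$zf
  groups <- collapse_to_groups(sim$counts, fx$table, "zf")
  audit <- attr(groups, "audit")
  to_group <- function(genes) unique(audit$group_id[match(
    intersect(genes, audit$gene_id), audit$gene_id)])
  cl <- sim$truth$cluster
  # set planted in cluster 1
  set1 <- to_group(sim$truth$marker_sets[[1]])
  call1 <- geneset_enrichment_by_cluster(groups, cl, set1, n_perm = 100L,
                                         seed = 2L)
  expect_equal(call1$call, "co-expressed")
  expect_equal(as.integer(call1$top_cluster), 1L)
  # set split between clusters 1 and 2
  split <- c(to_group(sim$truth$marker_sets[[1]])[1:12],
             to_group(sim$truth$marker_sets[[2]])[1:12])
  call2 <- geneset_enrichment_by_cluster(groups, cl, split, n_perm = 100L,
                                         seed = 3L)
  expect_true(call2$call %in% c("spread", "co-expressed"))
  expect_equal(call2$call, "spread")
  # tiny coverage: not evaluable
  tiny <- geneset_enrichment_by_cluster(groups, cl, set1[1:2])
  expect_equal(tiny$call, "not evaluable")
})

test_that("random gene sets are called absent almost always", {
  # null calibration: no planted expression difference between the
  # labeled groups, so any call other than "absent" is a false positive
  sim <- generate_counts(sim_config(n_cells = 250L, n_genes = 300L,
                                    n_clusters = 4L, marker_logfc = 0,
                                    n_markers_per_cluster = 25L,
                                    seed = 68L))
  set.seed(67)
  calls <- vapply(1:20, function(i) {
    rs <- sample(rownames(sim$counts), 15L)
    geneset_enrichment_by_cluster(sim$counts, sim$truth$cluster, rs,
                                  n_perm = 60L, seed = i)$call
  }, character(1))
  expect_gte(mean(calls == "absent"), 0.9)
})
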