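# Shared fixtures, computed once per test run (memoized).

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# the standard planted fixture: 1,500 cells, 6 clusters, 30 markers each,
# natural-log fold change 2
std_fixture <- function() memo("std", function() {
  generate_counts(sim_config(n_cells = 1500L, n_genes = 2000L,
                             n_clusters = 6L, n_markers_per_cluster = 30L,
                             marker_logfc = 2, seed = 21L))
})

std_consensus <- function() memo("std_consensus", function() {
  consensus_cluster(std_fixture()$counts, seed = 22L)
})

# smaller planted fixture for module-level tests
small_fixture <- function() memo("small", function() {
  generate_counts(sim_config(n_cells = 400L, n_genes = 800L,
                             n_clusters = 3L, n_markers_per_cluster = 30L,
                             marker_logfc = 2, seed = 7L))
})

# trajectory fixture at the deep-sequencing (saturated-detection) study
# conditions: 800 cells, 40 + 40 depth-module genes, 2x end-to-end effect
traj_fixture <- function() memo("traj", function() {
  generate_trajectory_counts(sim_config(
    n_cells = 800L, n_genes = 600L, trajectory = TRUE,
    depth_module_size = 40L, depth_logfc = log(2), nb_dispersion = 10,
    libsize_mean = 8000, libsize_dispersion = 0.15, seed = 3L))
})

traj_deep_genes <- function(truth)
  sub("^\\+", "", grep("^[+]", truth$depth_genes, value = TRUE))
traj_shallow_genes <- function(truth)
  sub("^-", "", grep("^-", truth$depth_genes, value = TRUE))

# population-scoring fixture: named glial / ribosomal / neuroblast programs
# with biologically signed regulation (quiescence suppresses ribosomal
# genes, neuroblasts repress glial genes)
score_fixture <- function(n = 600L, seed = 31L) {
  key <- paste0("score", n, "_", seed)
  memo(key, function() {
    set.seed(seed)
    glial <- c("GFAP", "GLUL", "GJA1", "FABP7")
    nb <- c("NEUROD1", "NEUROD2", "NEUROD4", "NEUROD6", "STMN1", "DPYSL3",
            "GAP43", "BHLHE22", "TUBB5")
    ribo <- sprintf("rps%d", 1:20)
    genes <- c(glial, nb, ribo, sprintf("g%d", 1:400))
    pop <- sample(c("qRG", "paRG", "NB", "other"), n, replace = TRUE,
                  prob = c(0.2, 0.1, 0.2, 0.5))
    base <- exp(rnorm(length(genes), 0, 1))
    rates <- matrix(base, length(genes), n, dimnames = list(genes, NULL))
    up <- function(setg, cells, f)
      rates[setg, cells] <<- rates[setg, cells] * f
    up(glial, pop %in% c("qRG", "paRG"), 6)
    up(glial, pop == "NB", 0.15)
    up(ribo, pop %in% c("paRG", "NB"), 4)
    up(ribo, pop == "qRG", 0.2)
    up(nb, pop == "NB", 6)
    up(nb, pop %in% c("qRG", "paRG"), 0.2)
    lib <- exp(rnorm(n, log(3000), 0.15))
    mu <- sweep(sweep(rates, 2, colSums(rates), "/"), 2, lib, "*")
    cm <- matrix(rnbinom(length(mu), size = 10, mu = mu), nrow(mu),
                 dimnames = dimnames(mu))
    colnames(cm) <- sprintf("cell%d", seq_len(n))
    list(counts = methods::as(Matrix::Matrix(cm, sparse = TRUE),
                              "CsparseMatrix"),
         pop = pop)
  })
}

# simple Gaussian blob embedding fixture
blob_embedding <- function(n_per = 60L, centers, sd = 1, seed = 5L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[k, ], "+")))
}

spearman <- function(a, b) stats::cor(a, b, method = "spearman")
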