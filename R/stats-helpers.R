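# Internal statistical helpers shared across modules.

# Rank-based AUC of `score` for membership in `positive` (logical).
# Ties get mid-ranks, so AUC = (#concordant + 0.5 #ties) / (n1*n2).
.auroc <- function(score, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Vectorized Wilcoxon rank-sum across genes (rows of x), group1 vs group2
# cell indices; normal approximation with tie correction; two-sided.
# Returns data.frame(gene, p, log2fc, auc).
.wilcox_de <- function(x, cells1, cells2) {
  x1 <- x[, cells1, drop = FALSE]
  x2 <- x[, cells2, drop = FALSE]
  n1 <- length(cells1); n2 <- length(cells2)
  sub <- as.matrix(methods::cbind2(x1, x2))
  n <- n1 + n2
  stats_row <- function(v) {
    r <- rank(v, ties.method = "average")
    w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
    nt <- table(v)
    tie_term <- sum(nt^3 - nt)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    mu <- n1 * n2 / 2
    if (sigma2 <= 0) return(c(1, w / (n1 * n2)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    c(2 * stats::pnorm(-abs(z)), w / (n1 * n2))
  }
  st <- t(apply(sub, 1, stats_row))
  # log2 fold change of mean normalized expression (pseudocount 1 on
  # expm1 scale, matching common marker-test conventions)
  m1 <- Matrix::rowMeans(x1)
  m2 <- Matrix::rowMeans(x2)
  log2fc <- log2((expm1(m1) + 1) / (expm1(m2) + 1))
  data.frame(gene = rownames(x), p = st[, 1], log2fc = as.numeric(log2fc),
             auc = st[, 2], stringsAsFactors = FALSE, row.names = NULL)
}

# Shared DE criterion used by merging and doublet-cluster logic:
# Wilcoxon rank-sum, BH-FDR and absolute log2 fold-change cut.
.de_genes <- function(x, cells1, cells2, fdr = 0.05, min_log2fc = 0.25) {
  de <- .wilcox_de(x, cells1, cells2)
  de$q <- stats::p.adjust(de$p, method = "BH")
  de$significant <- de$q < fdr & abs(de$log2fc) >= min_log2fc
  de
}

# Dense labels 0..K-1, relabeled by decreasing cluster size (deterministic).
.dense_labels <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  match(as.character(labels), names(tab)) - 1L
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around \code{mclust::adjustedRandIndex}.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
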