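#' Read a count matrix
#'
#' Reads either a MatrixMarket triplet directory (\code{matrix.mtx},
#' \code{genes.tsv}, \code{barcodes.tsv}; standard 1-based indices handled
#' by the MatrixMarket reader) or a dense CSV with genes as rows.
#'
#' @param path directory with MTX triplet files, or a \code{.csv} file.
#' @return genes x cells dgCMatrix with dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    m <- Matrix::readMM(file.path(path, "matrix.mtx"))
    genes <- readLines(file.path(path, "genes.tsv"))
    cells <- readLines(file.path(path, "barcodes.tsv"))
    genes <- vapply(strsplit(genes, "\t"), `[`, "", 1L)
    cells <- vapply(strsplit(cells, "\t"), `[`, "", 1L)
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("dimension mismatch between matrix.mtx and tsv files")
    rownames(m) <- genes
    colnames(m) <- cells
    methods::as(m, "CsparseMatrix")
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE),
                "CsparseMatrix")
  } else stop("path must be an MTX directory or a .csv file")
}

#' Write a count matrix as an MTX triplet directory
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(counts, "generalMatrix"),
                              "TsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts)),
                     file.path(path, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(counts)),
                     file.path(path, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write tab-separated tables (clones, orthologs, truth)
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @param table data.frame to write.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
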