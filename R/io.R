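#' Write a count matrix as MatrixMarket plus annotation TSVs
#'
#' Writes `matrix.mtx` (genes x cells, sparse MatrixMarket), `genes.tsv`
#' (`gene_id`, `chromosome`) and `cells.tsv` (`cell_id`); for a simulation
#' object the truth tables `truth_cells.csv` and `truth_copies.csv` are
#' written too.
#'
#' @param x An `aneu_sim_counts` object, or a gene x cell matrix.
#' @param dir Output directory (created if needed).
#' @param genes Tibble (`gene_id`, `chromosome`); required when `x` is a
#'   bare matrix.
#' @return Invisibly, the paths written.
#' @export
write_count_matrix <- function(x, dir, genes = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "aneu_sim_counts")) {
    counts <- x$counts
    genes <- x$genes
  } else {
    counts <- x
    if (is.null(genes)) abort("genes annotation required for a bare matrix")
  }
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"),
                  paths[1])
  readr::write_tsv(genes, paths[2], col_names = TRUE)
  readr::write_tsv(tibble::tibble(cell_id = colnames(counts)), paths[3])
  if (inherits(x, "aneu_sim_counts")) {
    readr::write_csv(x$truth, file.path(dir, "truth_cells.csv"))
    readr::write_csv(x$copies, file.path(dir, "truth_copies.csv"))
    paths <- c(paths, file.path(dir, c("truth_cells.csv", "truth_copies.csv")))
  }
  invisible(paths)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Also accepts a dense TSV (`counts_tsv`) whose first column is `gene_id`
#' and remaining columns are cells.
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @param counts_tsv Optional dense TSV path used instead of `dir`.
#' @param genes_tsv Genes TSV path when using `counts_tsv`.
#' @return List with `counts` (integer matrix) and `genes` (tibble).
#' @export
read_count_matrix <- function(dir = NULL, counts_tsv = NULL, genes_tsv = NULL) {
  if (!is.null(counts_tsv)) {
    d <- readr::read_tsv(counts_tsv, show_col_types = FALSE)
    counts <- as.matrix(d[, -1])
    rownames(counts) <- d[[1]]
    genes <- readr::read_tsv(genes_tsv, show_col_types = FALSE)
    return(list(counts = counts, genes = genes))
  }
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"), show_col_types = FALSE)
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  storage.mode(m) <- "integer"
  list(counts = m, genes = genes)
}

#' Read and write metaphase-spread count CSVs
#'
#' Plain CSV with columns `condition`, `count`.
#'
#' @param spreads Tibble (`condition`, `count`) or `aneu_sim_spreads`.
#' @param path CSV path.
#' @return `read_spreads` returns the tibble; `write_spreads` the path,
#'   invisibly.
#' @export
write_spreads <- function(spreads, path) {
  if (inherits(spreads, "aneu_sim_spreads")) spreads <- spreads$spreads
  readr::write_csv(spreads, path)
  invisible(path)
}

#' @rdname write_spreads
#' @export
read_spreads <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(), count = readr::col_integer()
  ))
}

#' Write and read multi-channel images as TIFF
#'
#' Channels are written as separate TIFF directories (pages) in 32-bit
#' float; intensities are stored as-is when within [0, 1], otherwise
#' rescaled by the image maximum (counting is ratio-based, so rescaling does
#' not affect results).
#'
#' @param img `aneu_sim_foci` object or 3D array (height x width x
#'   channels).
#' @param path TIFF path.
#' @return `write_foci_tiff` returns the path invisibly; `read_foci_tiff`
#'   the 3D array.
#' @export
write_foci_tiff <- function(img, path) {
  if (inherits(img, "aneu_sim_foci")) img <- img$image
  mx <- max(img)
  if (mx > 1) img <- img / mx
  pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_foci_tiff
#' @export
read_foci_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}
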