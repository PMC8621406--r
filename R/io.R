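#' Write a table as TSV with header
#' @param x data.frame
#' @param path output file
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with header
#' @param path input file
#' @return data.frame (characters kept as characters)
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = NA)
}

#' Write labeled counts as MatrixMarket plus gene/cell TSVs
#'
#' Writes `counts.mtx` (cells x genes), `genes.tsv` (one gene id per line),
#' and `cells.tsv` (cell_id, cell_type) into `dir`.
#'
#' @param data a [labeled_counts()] object.
#' @param dir output directory (created if missing).
#' @export
write_labeled_counts <- function(data, dir) {
  stopifnot(inherits(data, "labeled_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(data$counts, "CsparseMatrix"),
                  file.path(dir, "counts.mtx"))
  writeLines(colnames(data$counts), file.path(dir, "genes.tsv"))
  write_tsv(data.frame(cell_id = rownames(data$counts),
                       cell_type = data$cell_types),
            file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read labeled counts written by [write_labeled_counts()]
#' @param dir directory holding counts.mtx, genes.tsv, cells.tsv.
#' @return a [labeled_counts()] object.
#' @export
read_labeled_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "counts.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  dimnames(m) <- list(cells$cell_id, genes)
  labeled_counts(m, cells)
}
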