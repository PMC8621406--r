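#' Construct a labeled count matrix
#'
#' Bundles a cell x gene count matrix with one germline cell-type label per
#' cell. Counts may be a base matrix or any Matrix class; they are stored
#' sparse.
#'
#' @param counts cell x gene non-negative count matrix with unique column
#'   (gene) names.
#' @param cell_labels data.frame with columns `cell_id`, `cell_type`;
#'   cell_type values must come from [GERMLINE_CELL_TYPES]. Row order must
#'   match the matrix rows (matched by `cell_id` when row names are present).
#' @return object of class `labeled_counts`: list(counts, cell_types).
#' @export
labeled_counts <- function(counts, cell_labels) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("counts must have unique gene (column) names")
  if (!all(c("cell_id", "cell_type") %in% names(cell_labels)))
    stop("cell_labels needs columns cell_id, cell_type")
  if (nrow(cell_labels) != nrow(counts))
    stop("one cell_type label required per cell: ", nrow(counts), " cells, ",
         nrow(cell_labels), " labels")
  if (!is.null(rownames(counts))) {
    idx <- match(rownames(counts), cell_labels$cell_id)
    if (anyNA(idx)) stop("cell labels missing for some cells")
    cell_labels <- cell_labels[idx, ]
  } else {
    rownames(counts) <- cell_labels$cell_id
  }
  bad <- setdiff(unique(cell_labels$cell_type), GERMLINE_CELL_TYPES)
  if (length(bad))
    stop("unknown cell types: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts,
                 cell_types = cell_labels$cell_type),
            class = "labeled_counts")
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat("labeled_counts:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  print(table(x$cell_types))
  invisible(x)
}

#' Concatenate labeled count matrices from multiple samples
#'
#' Stacks cells from several [labeled_counts()] objects over the union of
#' their genes (missing genes zero-filled). No batch correction of any kind
#' is applied — a warning says so — because per-cell CPM normalization
#' downstream only corrects depth, not between-sample composition effects.
#'
#' @param ... two or more [labeled_counts()] objects with globally unique
#'   cell ids.
#' @return a single [labeled_counts()] object.
#' @export
combine_labeled_counts <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 2,
            all(vapply(parts, inherits, logical(1), "labeled_counts")))
  genes <- Reduce(union, lapply(parts, function(p) colnames(p$counts)))
  mats <- lapply(parts, function(p) {
    m <- Matrix::Matrix(0, nrow = nrow(p$counts), ncol = length(genes),
                        sparse = TRUE,
                        dimnames = list(rownames(p$counts), genes))
    m[, colnames(p$counts)] <- p$counts
    m
  })
  cells <- do.call(rbind, lapply(parts, function(p)
    data.frame(cell_id = rownames(p$counts), cell_type = p$cell_types,
               stringsAsFactors = FALSE)))
  if (anyDuplicated(cells$cell_id))
    stop("cell ids must be unique across samples")
  warning("samples concatenated without batch correction")
  labeled_counts(do.call(rbind, mats), cells)
}

#' Quality-control filter on genes and cells
#'
#' Keeps genes detected (count > 0) in at least `min_cells` cells and cells
#' with at least `min_genes` detected genes. Both masks are computed on the
#' input matrix and applied jointly in one pass; set `iterate = TRUE` to
#' re-apply the two filters until a fixed point.
#'
#' @param data a [labeled_counts()] object.
#' @param min_cells minimum cells a gene must be detected in (default 3).
#' @param min_genes minimum detected genes a cell must have (default 200).
#' @param iterate re-filter until stable instead of the single joint pass.
#' @return filtered [labeled_counts()]; warns if no gene or cell survives.
#' @export
qc_filter <- function(data, min_cells = 3L, min_genes = 200L,
                      iterate = FALSE) {
  stopifnot(inherits(data, "labeled_counts"))
  m <- data$counts
  if (!length(m)) stop("empty count matrix")
  repeat {
    detected <- m > 0
    keep_gene <- Matrix::colSums(detected) >= min_cells
    keep_cell <- Matrix::rowSums(detected) >= min_genes
    m2 <- m[keep_cell, keep_gene, drop = FALSE]
    types <- data$cell_types[keep_cell]
    done <- !iterate ||
      (all(Matrix::colSums(m2 > 0) >= min_cells | ncol(m2) == 0) &&
       all(Matrix::rowSums(m2 > 0) >= min_genes | nrow(m2) == 0))
    m <- m2
    data$cell_types <- types
    if (done) break
  }
  if (nrow(m) == 0 || ncol(m) == 0)
    warning("QC filter removed all ",
            if (nrow(m) == 0) "cells" else "genes")
  data$counts <- m
  data
}

#' Aggregate counts into per-gene stage profiles
#'
#' Normalizes each cell to counts per million (CPM, over the genes present in
#' the matrix), then for every gene and germline cell type computes the mean
#' log2(CPM + 1) over that type's cells and the percentage of that type's
#' cells in which the gene is detected (count > 0).
#'
#' @param data a QC-filtered [labeled_counts()]; all four germline cell types
#'   must be present.
#' @return `stage_profile` data.frame: gene_id, mean_<cell type> and
#'   pct_<cell type> columns (means in log2(CPM+1), percentages in 0..100).
#' @export
aggregate_profiles <- function(data) {
  stopifnot(inherits(data, "labeled_counts"))
  missing_ct <- setdiff(GERMLINE_CELL_TYPES, unique(data$cell_types))
  if (length(missing_ct))
    stop("germline cell type(s) absent from input: ",
         paste(missing_ct, collapse = ", "))
  m <- data$counts
  depth <- Matrix::rowSums(m)
  if (any(depth == 0)) stop("cells with zero total counts; run qc_filter first")
  dense <- as.matrix(m)
  logcpm <- log2(sweep(dense, 1, 1e6 / depth, "*") + 1)  # cell x gene
  res <- data.frame(gene_id = colnames(m), stringsAsFactors = FALSE)
  for (ct in GERMLINE_CELL_TYPES) {
    rows <- data$cell_types == ct
    res[[paste0("mean_", ct)]] <- colMeans(logcpm[rows, , drop = FALSE])
    res[[paste0("pct_", ct)]] <-
      100 * colMeans(dense[rows, , drop = FALSE] > 0)
  }
  class(res) <- c("stage_profile", "data.frame")
  res
}

#' Extract the mean-expression or percent-expressed matrix from a profile
#' @param profile a `stage_profile` data.frame.
#' @param what "mean" or "pct".
#' @return numeric gene x cell-type matrix with gene_id row names.
#' @export
profile_matrix <- function(profile, what = c("mean", "pct")) {
  what <- match.arg(what)
  cols <- paste0(what, "_", GERMLINE_CELL_TYPES)
  if (!all(cols %in% names(profile)))
    stop("profile lacks columns: ",
         paste(setdiff(cols, names(profile)), collapse = ", "))
  m <- as.matrix(profile[, cols])
  dimnames(m) <- list(profile$gene_id, GERMLINE_CELL_TYPES)
  m
}
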