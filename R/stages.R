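#' @importFrom stats dist hclust cutree fisher.test pchisq p.adjust rnbinom
#'   rpois sd setNames
#' @importFrom utils read.delim write.table
#' @importFrom methods as
NULL

#' Germline cell types of Drosophila spermatogenesis, in developmental order
#'
#' Spermatogonia divide mitotically, early and late (primary) spermatocytes
#' go through meiosis, and spermatids are the post-meiotic haploid cells.
#' All gene-by-cell-type vectors in this package follow this order.
#'
#' @export
GERMLINE_CELL_TYPES <- c("spermatogonia", "early_spermatocytes",
                         "late_spermatocytes", "spermatids")

#' Spermatogenesis stage categories
#'
#' The five categories of germline-expressed genes, named after the stage(s)
#' of their predominant expression, plus `NOT_EXPRESSED` for genes silent in
#' all four germline cell types. The order here is developmental.
#'
#' @export
STAGE_CATEGORIES <- c("NOT_EXPRESSED", "MITOSIS", "MITOSIS_MEIOSIS",
                      "MEIOSIS", "MEIOSIS_POSTMEIOSIS", "POSTMEIOSIS")

#' Drosophila melanogaster chromosome arms used throughout
#' @export
CHROMOSOMES <- c("2L", "2R", "3L", "3R", "4", "X", "Y")

#' Major autosome arms ("autosomes excluding the dot chromosome")
#' @export
AUTOSOMES <- c("2L", "2R", "3L", "3R")

.category_ranks <- c(NOT_EXPRESSED = NA_integer_, MITOSIS = 1L,
                     MITOSIS_MEIOSIS = 2L, MEIOSIS = 3L,
                     MEIOSIS_POSTMEIOSIS = 4L, POSTMEIOSIS = 4L)

.category_cells <- list(
  MITOSIS             = "spermatogonia",
  MITOSIS_MEIOSIS     = c("spermatogonia", "early_spermatocytes"),
  MEIOSIS             = c("early_spermatocytes", "late_spermatocytes"),
  MEIOSIS_POSTMEIOSIS = c("late_spermatocytes", "spermatids"),
  POSTMEIOSIS         = "spermatids"
)

#' Stage rank of a category
#'
#' Ranks run 1 (mitosis) to 4 (meiosis-and-post-meiosis) along spermatogenesis
#' and are the values differenced by [shift_score()]. `POSTMEIOSIS` shares
#' rank 4 with `MEIOSIS_POSTMEIOSIS` because the post-meiotic category holds
#' too few genes to stand alone and downstream tests pool the two.
#' `NOT_EXPRESSED` has no rank (`NA`).
#'
#' @param category character vector of values from [STAGE_CATEGORIES].
#' @return integer vector of ranks in 1..4, `NA` for `NOT_EXPRESSED`.
#' @export
#' @examples
#' category_rank(c("MITOSIS", "POSTMEIOSIS", "NOT_EXPRESSED"))
category_rank <- function(category) {
  bad <- !is.na(category) & !category %in% names(.category_ranks)
  if (any(bad))
    stop("unknown stage category: ", paste(unique(category[bad]), collapse = ", "))
  unname(.category_ranks[as.character(category)])
}

#' Cell types in which a stage category is predominantly expressed
#'
#' @param category a single value from [STAGE_CATEGORIES] (not `NOT_EXPRESSED`).
#' @return character vector of cell types from [GERMLINE_CELL_TYPES].
#' @export
category_cells <- function(category) {
  if (!category %in% names(.category_cells))
    stop("no cell-type set for category: ", category)
  .category_cells[[category]]
}

#' Convert a stage rank back to a representative category
#' @param rank integer vector in 1..4
#' @return character vector of categories (rank 4 maps to MEIOSIS_POSTMEIOSIS)
#' @keywords internal
rank_category <- function(rank) {
  stopifnot(all(rank %in% 1:4))
  c("MITOSIS", "MITOSIS_MEIOSIS", "MEIOSIS", "MEIOSIS_POSTMEIOSIS")[rank]
}
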