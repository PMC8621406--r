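#' Stage-shift score between a parental and a new gene
#'
#' The four expressed stage categories are ranked 1 (mitosis) to 4
#' (meiosis-and-post-meiosis) along spermatogenesis; the shift is the child's
#' rank minus the parent's. Positive values mean the new gene is expressed
#' later in spermatogenesis than its parent; a parent in spermatogonia
#' (rank 1) with a child in rank 4 cells scores +3.
#'
#' @param parent_rank,child_rank integer vectors of ranks in 1..4 (`NA`
#'   allowed for unexpressed genes, which yield `NA`).
#' @return integer vector of shifts in -3..3.
#' @export
shift_score <- function(parent_rank, child_rank) {
  ok <- function(r) all(is.na(r) | (r %in% 1:4))
  if (!ok(parent_rank) || !ok(child_rank))
    stop("ranks must be in 1..4 or NA")
  as.integer(child_rank) - as.integer(parent_rank)
}

#' Directional class of a stage shift
#'
#' Classifies a (parent rank, child rank) pair into one of four directions:
#' `INTO_MEIOSIS` when a mitotic-stage parent (rank 1 or 2) produced a
#' meiotic-stage child (rank 3 or 4); `INTO_MITOSIS` for the reverse
#' crossing; `WITHIN_MITOTIC` / `WITHIN_MEIOTIC` when both genes stay on the
#' same side of the mitosis/meiosis boundary. The four classes partition all
#' 16 rank pairs; pairs with an unexpressed member (`NA` rank) are
#' `UNCLASSIFIED`.
#'
#' @inheritParams shift_score
#' @return character vector of direction classes.
#' @export
classify_shift <- function(parent_rank, child_rank) {
  shift_score(parent_rank, child_rank)  # validates ranks
  n <- max(length(parent_rank), length(child_rank))
  parent_rank <- rep_len(parent_rank, n)
  child_rank <- rep_len(child_rank, n)
  p_mit <- parent_rank %in% 1:2
  c_mit <- child_rank %in% 1:2
  out <- ifelse(p_mit & !c_mit, "INTO_MEIOSIS",
         ifelse(!p_mit & c_mit, "INTO_MITOSIS",
         ifelse(p_mit & c_mit, "WITHIN_MITOTIC", "WITHIN_MEIOTIC")))
  out[is.na(parent_rank) | is.na(child_rank)] <- "UNCLASSIFIED"
  out
}

#' Derive the chromosomal route of a parent/new-gene pair
#'
#' @param parent_chrom,child_chrom chromosome of parent and child; parent
#'   `NA` (de novo genes) gives route `de_novo`.
#' @return character vector: `A_to_A_intra`, `A_to_A_inter`, `A_to_X`,
#'   `X_to_A`, `X_to_X`, `de_novo`, or `other` (any pair involving Y or the
#'   dot chromosome).
#' @export
derive_route <- function(parent_chrom, child_chrom) {
  n <- max(length(parent_chrom), length(child_chrom))
  parent_chrom <- rep_len(parent_chrom, n)
  child_chrom <- rep_len(child_chrom, n)
  pA <- parent_chrom %in% AUTOSOMES
  cA <- child_chrom %in% AUTOSOMES
  pX <- !is.na(parent_chrom) & parent_chrom == "X"
  cX <- !is.na(child_chrom) & child_chrom == "X"
  out <- rep("other", n)
  same <- !is.na(parent_chrom) & !is.na(child_chrom) &
    parent_chrom == child_chrom
  out[pA & cA & same] <- "A_to_A_intra"
  out[pA & cA & !same] <- "A_to_A_inter"
  out[pA & cX] <- "A_to_X"
  out[pX & cA] <- "X_to_A"
  out[pX & cX] <- "X_to_X"
  out[is.na(parent_chrom)] <- "de_novo"
  out
}

#' Build per-pair shift records
#'
#' Joins a pair table with per-gene stage categories and annotations,
#' derives each pair's chromosomal route, and scores and classifies its
#' stage shift. Pairs in which either gene is unexpressed (or absent from
#' the category table) get `NA` shift and class `UNCLASSIFIED`.
#'
#' @param pairs data.frame with child_id, parent_id (NA for de novo),
#'   branch, mechanism columns.
#' @param categories data.frame (gene_id, category) from [classify_stages()].
#' @param annotations data.frame with gene_id, chromosome.
#' @return data.frame: the pair columns plus route, parent_category,
#'   child_category, parent_rank, child_rank, shift, direction.
#' @export
build_shift_records <- function(pairs, categories, annotations) {
  cat_of <- setNames(categories$category, categories$gene_id)
  chrom_of <- setNames(annotations$chromosome, annotations$gene_id)
  parent_category <- unname(cat_of[pairs$parent_id])
  child_category <- unname(cat_of[pairs$child_id])
  parent_rank <- category_rank(parent_category)
  child_rank <- category_rank(child_category)
  res <- data.frame(
    child_id = pairs$child_id,
    parent_id = pairs$parent_id,
    branch = pairs$branch,
    mechanism = pairs$mechanism,
    route = derive_route(unname(chrom_of[pairs$parent_id]),
                         unname(chrom_of[pairs$child_id])),
    parent_category = parent_category,
    child_category = child_category,
    parent_rank = parent_rank,
    child_rank = child_rank,
    shift = shift_score(parent_rank, child_rank),
    direction = classify_shift(parent_rank, child_rank),
    stringsAsFactors = FALSE
  )
  res
}

#' Fraction of pairs expressed in completely non-overlapping cell types
#'
#' A pair counts as non-overlapping when the cell-type sets of the parent's
#' and the child's categories are disjoint (e.g., mitosis {spermatogonia}
#' vs post-meiosis {spermatids}). Only pairs with both genes expressed are
#' eligible; a stratum with no eligible pair yields `NA`.
#'
#' @param records data.frame from [build_shift_records()].
#' @param by optional column name to stratify by (e.g. "branch"); `NULL`
#'   computes one overall percentage.
#' @return named numeric vector of percentages in 0..100.
#' @export
nonoverlap_fraction <- function(records, by = NULL) {
  eligible <- !is.na(records$parent_rank) & !is.na(records$child_rank)
  disjoint <- rep(NA, nrow(records))
  for (i in which(eligible)) {
    disjoint[i] <- !length(intersect(
      category_cells(records$parent_category[i]),
      category_cells(records$child_category[i])))
  }
  if (is.null(by))
    return(c(all = 100 * mean(disjoint[eligible])))
  strata <- split(seq_len(nrow(records)), records[[by]])
  vapply(strata, function(i) {
    e <- i[eligible[i]]
    if (!length(e)) return(NA_real_)
    100 * mean(unlist(disjoint[e]))
  }, numeric(1))
}

#' Compare the stage-category composition of two gene sets
#'
#' For each stage category (meiotic categories pooled when requested), a
#' two-sided Fisher exact test of the 2x2 table (in category vs not) x
#' (set A vs set B). Used between new genes and their parents per stratum,
#' and between de novo genes and the genomic background.
#'
#' @param cats_a,cats_b character vectors of stage categories for the two
#'   sets (e.g. children vs parents). `NOT_EXPRESSED` entries are dropped.
#' @param pool_meiosis pool MEIOSIS, MEIOSIS_POSTMEIOSIS and POSTMEIOSIS.
#' @param stratum label copied into the output rows.
#' @return data.frame of [fisher_2x2()] rows, one per tested category;
#'   direction "enriched" means set A has the higher proportion.
#' @export
composition_compare <- function(cats_a, cats_b, pool_meiosis = TRUE,
                                stratum = NA_character_) {
  cats_a <- cats_a[!is.na(cats_a) & cats_a != "NOT_EXPRESSED"]
  cats_b <- cats_b[!is.na(cats_b) & cats_b != "NOT_EXPRESSED"]
  if (!length(cats_a) || !length(cats_b))
    stop("both gene sets must contain expressed genes")
  test_cats <- if (pool_meiosis) c("MITOSIS", "MITOSIS_MEIOSIS", "MEIOSIS")
               else setdiff(STAGE_CATEGORIES, "NOT_EXPRESSED")
  rows <- lapply(test_cats, function(ca) {
    grp <- .category_group(ca, pool_meiosis)
    fisher_2x2(sum(cats_a %in% grp), sum(!cats_a %in% grp),
               sum(cats_b %in% grp), sum(!cats_b %in% grp),
               stratum = stratum, category = paste(grp, collapse = "+"))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Shift spectrum per stratum
#'
#' Distribution of shift values (-3..3) and percentages of the four
#' direction classes for each (route, mechanism) stratum (or any other
#' stratification). Percentages are over classified pairs (both genes
#' expressed); the count of unclassified pairs is reported alongside.
#'
#' @param records data.frame from [build_shift_records()].
#' @param by character vector of stratifying columns (default route and
#'   mechanism).
#' @return data.frame, one row per stratum: the stratum columns, n pairs,
#'   n_unclassified, shift_m3..shift_p3 histogram columns, and
#'   pct_into_meiosis, pct_into_mitosis, pct_within_mitotic,
#'   pct_within_meiotic.
#' @export
shift_spectrum <- function(records, by = c("route", "mechanism")) {
  key <- interaction(records[by], drop = TRUE, sep = ":")
  strata <- split(seq_len(nrow(records)), key)
  shift_levels <- -3:3
  rows <- lapply(names(strata), function(s) {
    i <- strata[[s]]
    r <- records[i, ]
    classified <- r$direction != "UNCLASSIFIED"
    hist <- table(factor(r$shift[classified], levels = shift_levels))
    pct <- function(cl) if (any(classified))
      100 * mean(r$direction[classified] == cl) else NA_real_
    out <- r[1, by, drop = FALSE]
    out$n <- nrow(r)
    out$n_unclassified <- sum(!classified)
    for (v in shift_levels)
      out[[paste0("shift_", ifelse(v < 0, paste0("m", -v),
                                   ifelse(v == 0, "0", paste0("p", v))))]] <-
        as.integer(hist[as.character(v)])
    out$pct_into_meiosis <- pct("INTO_MEIOSIS")
    out$pct_into_mitosis <- pct("INTO_MITOSIS")
    out$pct_within_mitotic <- pct("WITHIN_MITOTIC")
    out$pct_within_meiotic <- pct("WITHIN_MEIOTIC")
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
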