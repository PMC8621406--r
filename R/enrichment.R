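#' Count genes by chromosome and stage category
#'
#' Dense contingency counts over all chromosomes and all categories
#' (including `NOT_EXPRESSED`): absent combinations are 0, never missing.
#' Genes without an annotation row, or annotated to an unknown chromosome,
#' are dropped with a warning listing them.
#'
#' @param categories data.frame (gene_id, category) from [classify_stages()].
#' @param annotations data.frame with gene_id and chromosome columns.
#' @return integer matrix, [CHROMOSOMES] x [STAGE_CATEGORIES].
#' @export
count_by_chrom <- function(categories, annotations) {
  chrom <- annotations$chromosome[match(categories$gene_id,
                                        annotations$gene_id)]
  bad <- is.na(chrom) | !chrom %in% CHROMOSOMES
  if (any(bad)) {
    warning(sum(bad), " gene(s) without a usable chromosome excluded: ",
            paste(utils::head(categories$gene_id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ...")
    categories <- categories[!bad, ]
    chrom <- chrom[!bad]
  }
  tab <- table(factor(chrom, levels = CHROMOSOMES),
               factor(categories$category, levels = STAGE_CATEGORIES))
  m <- matrix(as.integer(tab), nrow = length(CHROMOSOMES),
              dimnames = list(CHROMOSOMES, STAGE_CATEGORIES))
  m
}

.category_group <- function(category, pool_meiosis) {
  if (pool_meiosis &&
      category %in% c("MEIOSIS", "MEIOSIS_POSTMEIOSIS", "POSTMEIOSIS"))
    return(c("MEIOSIS", "MEIOSIS_POSTMEIOSIS", "POSTMEIOSIS"))
  category
}

#' Fisher exact test of a category's enrichment on a chromosome vs autosomes
#'
#' Tests whether `chrom` carries a different proportion of `category` genes
#' than the major autosomes (2L, 2R, 3L, 3R) with a two-sided Fisher exact
#' test on the 2x2 table of (in category / other expressed) x (chrom /
#' autosomes). Because post-meiotic genes are few, the meiosis,
#' meiosis-and-post-meiosis and post-meiosis categories are pooled when
#' `pool_meiosis = TRUE` and `category` is one of them. `NOT_EXPRESSED`
#' genes are excluded unless `category = "NOT_EXPRESSED"`, in which case the
#' test is expressed-vs-not.
#'
#' @param counts matrix from [count_by_chrom()].
#' @param chrom chromosome to test (not one of the major autosomes).
#' @param category stage category to test.
#' @param pool_meiosis pool the meiotic and post-meiotic categories.
#' @return data.frame row: stratum, category, a, b, c, d (the 2x2 table:
#'   a,b = in-category/other on `chrom`; c,d = on autosomes), odds_ratio
#'   (sample estimate ad/bc), p (two-sided Fisher), direction.
#' @export
fisher_vs_autosomes <- function(counts, chrom, category,
                                pool_meiosis = TRUE) {
  stopifnot(chrom %in% rownames(counts), category %in% colnames(counts))
  if (chrom %in% AUTOSOMES)
    stop("chrom must not be one of the reference autosomes")
  cat_cols <- .category_group(category, pool_meiosis)
  universe <- if (category == "NOT_EXPRESSED") colnames(counts)
              else setdiff(colnames(counts), "NOT_EXPRESSED")
  other_cols <- setdiff(universe, cat_cols)
  a <- sum(counts[chrom, cat_cols])
  b <- sum(counts[chrom, other_cols])
  cc <- sum(counts[AUTOSOMES, cat_cols])
  d <- sum(counts[AUTOSOMES, other_cols])
  fisher_2x2(a, b, cc, d, stratum = chrom,
             category = paste(cat_cols, collapse = "+"))
}

#' Two-sided Fisher exact test on a 2x2 table with direction
#'
#' @param a,b,c,d cell counts: rows are the two groups compared, columns are
#'   in-category vs not.
#' @param stratum,category labels copied into the result.
#' @return one-row data.frame: stratum, category, a..d, odds_ratio (sample
#'   ad/bc), p, direction ("enriched" if the first group's odds are higher,
#'   "depleted" if lower, "none" on a zero-margin table, where p is 1).
#' @export
fisher_2x2 <- function(a, b, c, d, stratum = NA_character_,
                       category = NA_character_) {
  tab <- matrix(c(a, c, b, d), nrow = 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p <- 1
    or <- NA_real_
    direction <- "none"
  } else {
    p <- fisher.test(tab, alternative = "two.sided")$p.value
    or <- (a * d) / (b * c)
    direction <- if (or > 1) "enriched" else if (or < 1) "depleted" else "none"
  }
  data.frame(stratum = stratum, category = category,
             a = a, b = b, c = c, d = d,
             odds_ratio = or, p = p, direction = direction,
             stringsAsFactors = FALSE)
}

#' Enrichment table over all non-reference chromosomes and categories
#'
#' Runs [fisher_vs_autosomes()] for every chromosome outside the reference
#' autosome set crossed with every expressed category (meiotic categories
#' pooled once when requested), and appends Benjamini-Hochberg adjusted
#' q-values over that family of tests. Significance flags in this kind of
#' table are conventionally driven by the raw p; the q column is reported
#' alongside.
#'
#' @param counts matrix from [count_by_chrom()].
#' @param pool_meiosis pool meiotic and post-meiotic categories.
#' @return data.frame of [fisher_2x2()] rows plus a `q` column.
#' @export
enrichment_table <- function(counts, pool_meiosis = TRUE) {
  chroms <- setdiff(rownames(counts), AUTOSOMES)
  cats <- if (pool_meiosis) c("MITOSIS", "MITOSIS_MEIOSIS", "MEIOSIS")
          else setdiff(colnames(counts), "NOT_EXPRESSED")
  rows <- list()
  for (ch in chroms)
    for (ca in cats)
      rows[[paste(ch, ca)]] <-
        fisher_vs_autosomes(counts, ch, ca, pool_meiosis = pool_meiosis)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Normalized per-chromosome category ratio vs autosomes
#'
#' The per-chromosome proportion of genes in a category divided by the same
#' proportion on the major autosomes:
#' (n\[cat, chrom\] / n\[chrom\]) / (n\[cat, A\] / n\[A\]). A value of 2
#' means the category is twice as prevalent on `chrom` as on the autosomes.
#' Undefined ratios (empty chromosome, category absent from autosomes) are
#' returned as `NA`.
#'
#' @inheritParams fisher_vs_autosomes
#' @param include_not_expressed count `NOT_EXPRESSED` genes in the
#'   denominators (default FALSE: proportions are over expressed genes).
#' @return numeric ratio (possibly `NA`).
#' @export
normalized_ratio <- function(counts, chrom, category, pool_meiosis = FALSE,
                             include_not_expressed = FALSE) {
  stopifnot(chrom %in% rownames(counts), category %in% colnames(counts))
  cat_cols <- .category_group(category, pool_meiosis)
  universe <- if (include_not_expressed) colnames(counts)
              else setdiff(colnames(counts), "NOT_EXPRESSED")
  n_cat_c <- sum(counts[chrom, cat_cols])
  n_c <- sum(counts[chrom, universe])
  n_cat_a <- sum(counts[AUTOSOMES, cat_cols])
  n_a <- sum(counts[AUTOSOMES, universe])
  if (n_c == 0 || n_cat_a == 0 || n_a == 0) return(NA_real_)
  (n_cat_c / n_c) / (n_cat_a / n_a)
}
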