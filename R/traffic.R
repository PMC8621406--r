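#' Expected inter-chromosomal gene traffic under the null
#'
#' Null model for where duplicated (retroposed) gene copies land: the chance
#' that a pair originates on chromosome i is proportional to i's share of
#' parental genes (g), and the chance that the copy inserts on chromosome j
#' is proportional to j's share of genomic sequence (L). So
#' E\[i -> j\] = N * (g_i / sum g) * (L_j / sum L). With
#' `exclude_intra = TRUE` (retroposition treated as inter-chromosomal) the
#' diagonal is zeroed and each row renormalized so row totals, and hence the
#' grand total N, are preserved. An empirical target-frequency vector can be
#' supplied in place of lengths.
#'
#' @param N total number of pairs.
#' @param g named vector of per-chromosome parental gene counts.
#' @param L named vector of per-chromosome lengths in bp (or any target
#'   weight, e.g. observed insertion frequencies), same names as `g`.
#' @param exclude_intra zero and renormalize the diagonal (default TRUE).
#' @return numeric source x target matrix summing to N.
#' @export
expected_traffic <- function(N, g, L, exclude_intra = TRUE) {
  if (is.null(names(g)) || is.null(names(L)))
    stop("g and L must be named by chromosome")
  if (!setequal(names(g), names(L)))
    stop("g and L must cover the same chromosomes")
  L <- L[names(g)]
  if (sum(g) <= 0 || sum(L) <= 0) stop("g and L must have positive totals")
  if (any(g < 0) || any(L < 0)) stop("g and L must be non-negative")
  E <- N * outer(g / sum(g), L / sum(L))
  dimnames(E) <- list(names(g), names(g))
  if (exclude_intra) {
    row_tot <- rowSums(E)
    diag(E) <- 0
    rs <- rowSums(E)
    scale <- ifelse(rs > 0, row_tot / rs, 0)
    E <- E * scale
  }
  E
}

#' Observed source-by-target traffic counts from a pair table
#'
#' @param pairs data.frame with parent_id, child_id (and optionally a
#'   mechanism column to filter on, e.g. retrogenes only).
#' @param annotations data.frame with gene_id, chromosome.
#' @param mechanism optional mechanism to restrict to (e.g. "RNA").
#' @param chromosomes chromosomes to tabulate over.
#' @return integer source x target matrix.
#' @export
observed_traffic <- function(pairs, annotations, mechanism = NULL,
                             chromosomes = CHROMOSOMES) {
  if (!is.null(mechanism) && "mechanism" %in% names(pairs))
    pairs <- pairs[pairs$mechanism %in% mechanism, ]
  pairs <- pairs[!is.na(pairs$parent_id), ]
  chrom_of <- setNames(annotations$chromosome, annotations$gene_id)
  src <- factor(unname(chrom_of[pairs$parent_id]), levels = chromosomes)
  tgt <- factor(unname(chrom_of[pairs$child_id]), levels = chromosomes)
  tab <- table(src, tgt)
  matrix(as.integer(tab), nrow = length(chromosomes),
         dimnames = list(chromosomes, chromosomes))
}

#' Chi-square test for an out-of-the-X excess of gene traffic
#'
#' Collapses the observed and expected source x target matrices into classes
#' with a grouping function (default: X-source vs autosome-source, i.e.
#' "moved out of the X" vs "moved between autosomes/onto the X") and
#' computes the Pearson chi-square statistic sum((O - E)^2 / E) with
#' df = classes - 1. Expected class totals are rescaled to the observed
#' total, so only the null's proportions matter.
#'
#' @param observed integer matrix from [observed_traffic()].
#' @param expected numeric matrix from [expected_traffic()], same dimnames.
#' @param grouping function(source, target) returning a class label or `NA`
#'   to drop the cell; the default maps X-source cells to "out_of_X" and
#'   autosome-source cells to "from_autosomes", ignoring Y and the dot
#'   chromosome.
#' @return list: chi2, df, p, and the collapsed `classes` data.frame
#'   (class, observed, expected). Warns when any expected class count is
#'   below 1.
#' @export
out_of_x_test <- function(observed, expected, grouping = NULL) {
  stopifnot(identical(dim(observed), dim(expected)),
            identical(dimnames(observed), dimnames(expected)))
  if (is.null(grouping))
    grouping <- function(src, tgt) {
      if (src == tgt) return(NA_character_)
      if (src == "X" && tgt %in% AUTOSOMES) return("out_of_X")
      if (src %in% AUTOSOMES) return("from_autosomes")
      NA_character_
    }
  src <- rownames(observed)[row(observed)]
  tgt <- colnames(observed)[col(observed)]
  cls <- mapply(grouping, src, tgt)
  keep <- !is.na(cls)
  if (length(unique(cls[keep])) < 2)
    stop("grouping must produce at least 2 classes")
  O <- tapply(observed[keep], cls[keep], sum)
  E <- tapply(expected[keep], cls[keep], sum)
  E <- E * sum(O) / sum(E)
  if (any(E < 1))
    warning("expected count below 1 in class(es) ",
            paste(names(E)[E < 1], collapse = ", "), "; test unreliable")
  chi2 <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  p <- pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = unname(chi2), df = df, p = unname(p),
       classes = data.frame(class = names(O), observed = as.numeric(O),
                            expected = as.numeric(E),
                            stringsAsFactors = FALSE))
}
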