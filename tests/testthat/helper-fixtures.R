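# shared fixtures and independent oracles

# a pair design scaled down to suit universes of ~25 genes per archetype
small_design <- function() {
  d <- default_pair_design()
  d$n_pairs <- c(12L, 5L, 2L, 3L, 3L, 2L, 3L, 1L, 6L)
  d
}

# small labeled_counts from a dense matrix (cells x genes)
toy_counts <- function(mat, types) {
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("cell%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("gene%02d", seq_len(ncol(mat)))
  labeled_counts(mat, data.frame(cell_id = rownames(mat),
                                 cell_type = types,
                                 stringsAsFactors = FALSE))
}

# a tiny fully-compliant dataset: nc cells per type, ng genes, all detected
dense_compliant <- function(ng = 6, nc = 3, value = 5) {
  types <- rep(GERMLINE_CELL_TYPES, each = nc)
  m <- matrix(value, nrow = length(types), ncol = ng)
  toy_counts(m, types)
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (with the observed margins) no more
# likely than the observed one
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# upper chi-square tail by numerical integration of the density
chisq_p_integrate <- function(chi2, df) {
  integrate(function(x) dchisq(x, df), lower = chi2, upper = Inf,
            rel.tol = 1e-10)$value
}

# rule-table oracle for shift direction: literal transcription of the
# boundary-crossing taxonomy over mitotic ranks {1,2} and meiotic {3,4}
direction_oracle <- function(p, q) {
  if (p <= 2 && q >= 3) "INTO_MEIOSIS"
  else if (p >= 3 && q <= 2) "INTO_MITOSIS"
  else if (p <= 2 && q <= 2) "WITHIN_MITOTIC"
  else "WITHIN_MEIOTIC"
}

# planted-rank recovery of a pipeline run on synthetic truth, comparing
# stage ranks (post-meiotic categories pooled at rank 4) on expressed genes
rank_recovery <- function(result) {
  truth <- result$truth$labels
  m <- merge(truth, result$categories, by = "gene_id")
  expressed <- m$archetype != "NOT_EXPRESSED"
  planted <- category_rank(m$archetype[expressed])
  recovered <- category_rank(m$category[expressed])
  mean(!is.na(recovered) & planted == recovered)
}
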