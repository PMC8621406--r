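#' Row-scale an expression matrix to z-scores
#'
#' Centers each row to mean 0 and scales to sample standard deviation 1, the
#' transformation applied to per-gene log2(CPM+1) profiles before clustering
#' so that only the shape over cell types, not the expression magnitude,
#' drives the dendrogram. Rows with zero standard deviation (constant
#' profiles) map to all-zeros rather than NaN.
#'
#' @param m numeric gene x cell-type matrix.
#' @return matrix of the same shape, each row centered and scaled.
#' @export
scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  out <- (m - mu) / ifelse(s > 0, s, 1)
  out[s == 0, ] <- 0
  out
}

#' Hierarchical clustering of scaled stage profiles
#'
#' Complete-linkage agglomerative clustering on Euclidean distances between
#' row-scaled profiles, cut into `k` clusters. Genes are processed in
#' canonical (sorted gene-id) order so the merge tree, and therefore the
#' partition, does not depend on input order.
#'
#' @param scaled row-scaled gene x cell-type matrix with gene-id row names.
#' @param k number of clusters to cut the dendrogram into (default 7).
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector, gene -> cluster id in 1..k), `centroids` (k x cell-type matrix
#'   of mean scaled expression), `tree` (the hclust object).
#' @export
cluster_stages <- function(scaled, k = 7L) {
  if (is.null(rownames(scaled))) stop("scaled matrix needs gene-id row names")
  if (k < 1 || k > nrow(scaled))
    stop("k must be between 1 and the number of genes (", nrow(scaled), ")")
  ord <- order(rownames(scaled))
  scaled <- scaled[ord, , drop = FALSE]
  tree <- hclust(dist(scaled), method = "complete")
  cl <- cutree(tree, k = k)
  centroids <- t(vapply(split(seq_along(cl), cl), function(i)
    colMeans(scaled[i, , drop = FALSE]), numeric(ncol(scaled))))
  colnames(centroids) <- colnames(scaled)
  structure(list(cluster = cl, centroids = centroids, tree = tree),
            class = "cluster_assignment")
}

# the contiguous enriched sets recognized by the category rule, as index sets
# over GERMLINE_CELL_TYPES, and the category each maps to
.enriched_map <- list(
  list(set = 1L,        category = "MITOSIS"),
  list(set = 1:2,       category = "MITOSIS_MEIOSIS"),
  list(set = 2L,        category = "MEIOSIS"),
  list(set = 3L,        category = "MEIOSIS"),
  list(set = 2:3,       category = "MEIOSIS"),
  list(set = 3:4,       category = "MEIOSIS_POSTMEIOSIS"),
  list(set = 4L,        category = "POSTMEIOSIS")
)

.category_from_centroid <- function(centroid, theta = 0) {
  enriched <- unname(which(centroid > theta))
  hit <- Filter(function(e) identical(e$set, enriched), .enriched_map)
  if (length(hit)) return(list(category = hit[[1]]$category, fallback = FALSE))
  if (!length(enriched)) {
    # no cell type above threshold: fall back to the argmax cell type
    best <- unname(which.max(centroid))
    hit <- Filter(function(e) identical(e$set, best), .enriched_map)
    return(list(category = hit[[1]]$category, fallback = TRUE))
  }
  # non-contiguous or 3+-type set: nearest recognized set by centroid mass
  mass <- vapply(.enriched_map, function(e) mean(centroid[e$set]), numeric(1))
  list(category = .enriched_map[[which.max(mass)]]$category, fallback = TRUE)
}

#' Map clusters to spermatogenesis stage categories
#'
#' For each cluster, the cell types whose centroid (mean scaled expression)
#' exceeds `theta` form its enriched set; the set is mapped to a category:
#' spermatogonia-only is mitosis; spermatogonia plus early spermatocytes is
#' mitosis-and-meiosis; any spermatocyte-only set is meiosis; late
#' spermatocytes plus spermatids is meiosis-and-post-meiosis; spermatids-only
#' is post-meiosis. An empty enriched set falls back to the centroid's argmax
#' cell type, and a non-contiguous or 3+-type set to the recognized set with
#' the highest mean centroid mass; both fallbacks are flagged.
#'
#' @param assignment a [cluster_stages()] result.
#' @param theta enrichment threshold on the scaled centroid (default 0, i.e.
#'   above the gene's own mean).
#' @return data.frame: gene_id, cluster, category, with attribute
#'   `cluster_categories` (per-cluster category and fallback flag).
#' @export
assign_categories <- function(assignment, theta = 0) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  k <- nrow(assignment$centroids)
  per_cluster <- lapply(seq_len(k), function(i)
    .category_from_centroid(assignment$centroids[i, ], theta))
  cl_cat <- vapply(per_cluster, `[[`, character(1), "category")
  fallback <- vapply(per_cluster, `[[`, logical(1), "fallback")
  if (any(fallback))
    message("cluster(s) ", paste(which(fallback), collapse = ", "),
            " mapped by nearest-contiguous-set fallback")
  res <- data.frame(gene_id = names(assignment$cluster),
                    cluster = unname(assignment$cluster),
                    category = cl_cat[assignment$cluster],
                    stringsAsFactors = FALSE)
  attr(res, "cluster_categories") <-
    data.frame(cluster = seq_len(k), category = cl_cat, fallback = fallback)
  res
}

#' Classify genes into spermatogenesis stage categories
#'
#' Full classification pipeline: genes whose profile is all-zero are set
#' aside as `NOT_EXPRESSED`; the remaining rows are z-scaled, clustered
#' hierarchically (complete linkage, Euclidean distance), the dendrogram cut
#' into `k` clusters, and each cluster mapped to a stage category from its
#' centroid. `mode = "pct"` runs the identical pipeline on the
#' percent-expressing profile instead of mean log2(CPM+1), the robustness
#' variant of the categorization.
#'
#' @param profile a `stage_profile` from [aggregate_profiles()].
#' @param k clusters to cut (default 7).
#' @param mode "mean" (log2(CPM+1) averages) or "pct" (percent expressing).
#' @param theta centroid enrichment threshold, see [assign_categories()].
#' @return data.frame: gene_id, category, rank, cluster (cluster NA for
#'   `NOT_EXPRESSED` genes).
#' @export
classify_stages <- function(profile, k = 7L, mode = c("mean", "pct"),
                            theta = 0) {
  mode <- match.arg(mode)
  m <- profile_matrix(profile, mode)
  expressed <- rowSums(profile_matrix(profile, "mean")) > 0
  res <- data.frame(gene_id = rownames(m),
                    category = "NOT_EXPRESSED",
                    rank = NA_integer_,
                    cluster = NA_integer_,
                    stringsAsFactors = FALSE)
  if (any(expressed)) {
    scaled <- scale_rows(m[expressed, , drop = FALSE])
    kk <- min(k, nrow(scaled))
    assignment <- cluster_stages(scaled, k = kk)
    cats <- assign_categories(assignment, theta = theta)
    idx <- match(cats$gene_id, res$gene_id)
    res$category[idx] <- cats$category
    res$cluster[idx] <- cats$cluster
    res$rank[idx] <- category_rank(cats$category)
  }
  res
}

#' Agreement rate between the mean-based and percent-based categorizations
#'
#' @param profile a `stage_profile`.
#' @param k clusters to cut in both runs.
#' @param theta centroid enrichment threshold.
#' @return list: `agreement` (fraction of genes given the same category by
#'   both variants), `mean`, `pct` (the two classification tables).
#' @export
categorization_agreement <- function(profile, k = 7L, theta = 0) {
  a <- classify_stages(profile, k = k, mode = "mean", theta = theta)
  b <- classify_stages(profile, k = k, mode = "pct", theta = theta)
  stopifnot(identical(a$gene_id, b$gene_id))
  list(agreement = mean(a$category == b$category), mean = a, pct = b)
}
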