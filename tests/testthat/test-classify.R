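test_that("row scaling meets the z-score contracts", {
  m <- rbind(a = c(1, 1, 1, 1), b = c(0, 0, 0, 2), c = c(3, 1, 4, 1))
  s <- scale_rows(m)
  expect_equal(unname(s["a", ]), rep(0, 4))
  expect_equal(unname(s["b", ]), c(-0.5, -0.5, -0.5, 1.5))
  # every scaled row centered, unit sample SD unless constant
  expect_equal(unname(rowSums(s)), rep(0, 3))
  expect_equal(sd(s["c", ]), 1)
  expect_equal(sd(s["b", ]), 1)
})

test_that("complete-linkage clustering separates archetype blobs", {
  set.seed(31)
  blob <- function(center, n, id) {
    m <- matrix(rep(center, each = n), nrow = n) +
      matrix(rnorm(n * 4, sd = 0.05), nrow = n)
    rownames(m) <- sprintf("%s%02d", id, seq_len(n))
    m
  }
  m <- rbind(blob(c(2, 0, 0, 0), 10, "mit"), blob(c(0, 0, 0, 2), 10, "post"))
  cl <- cluster_stages(scale_rows(m), k = 2)$cluster
  expect_length(unique(cl[grep("mit", names(cl))]), 1)
  expect_length(unique(cl[grep("post", names(cl))]), 1)
  expect_equal(length(unique(cl)), 2)

  # k = n gives singletons; duplicated rows always co-cluster for k < n
  cl_n <- cluster_stages(scale_rows(m), k = 20)$cluster
  expect_equal(length(unique(cl_n)), 20)
  m2 <- m
  m2[2, ] <- m2[1, ]
  for (k in c(2, 5, 19)) {
    cl2 <- cluster_stages(scale_rows(m2), k = k)$cluster
    expect_equal(unname(cl2[1]), unname(cl2[2]))
  }

  expect_error(cluster_stages(scale_rows(m), k = 0), "between")
  expect_error(cluster_stages(scale_rows(m), k = 21), "between")
})

test_that("centroid enriched sets map to the documented categories", {
  fake_assignment <- function(centroids) {
    structure(list(cluster = setNames(seq_len(nrow(centroids)),
                                      sprintf("g%d", seq_len(nrow(centroids)))),
                   centroids = centroids, tree = NULL),
              class = "cluster_assignment")
  }
  centroids <- rbind(
    c(1.5, -0.5, -0.5, -0.5),   # spermatogonia only -> MITOSIS
    c(0.9, 1.0, -0.9, -1.0),    # spg + early spc -> MITOSIS_MEIOSIS
    c(-0.5, 1.5, -0.5, -0.5),   # early spc -> MEIOSIS
    c(-0.5, -0.5, 1.5, -0.5),   # late spc -> MEIOSIS
    c(-1.0, 0.9, 1.0, -0.9),    # both spc -> MEIOSIS
    c(-1.0, -0.9, 0.9, 1.0),    # late spc + spt -> MEIOSIS_POSTMEIOSIS
    c(-0.5, -0.5, -0.5, 1.5))   # spermatids -> POSTMEIOSIS
  colnames(centroids) <- GERMLINE_CELL_TYPES
  res <- assign_categories(fake_assignment(centroids))
  expect_equal(res$category,
               c("MITOSIS", "MITOSIS_MEIOSIS", "MEIOSIS", "MEIOSIS",
                 "MEIOSIS", "MEIOSIS_POSTMEIOSIS", "POSTMEIOSIS"))

  # non-contiguous set resolves to the nearest contiguous one and is flagged
  odd <- rbind(c(1.2, -1.0, 0.4, -0.6))
  colnames(odd) <- GERMLINE_CELL_TYPES
  expect_message(res2 <- assign_categories(fake_assignment(odd)), "fallback")
  expect_equal(res2$category, "MITOSIS")
  expect_true(attr(res2, "cluster_categories")$fallback)
})

test_that("classification partitions genes and conserves totals", {
  res <- run_pipeline(synth_config(seed = 13L))
  cats <- res$categories
  expect_equal(anyDuplicated(cats$gene_id), 0L)
  expect_equal(nrow(cats), res$manifest$n_genes_in)
  expect_equal(sum(unlist(res$manifest$category_counts)),
               res$manifest$n_genes_in)
  expect_true(all(cats$category %in% STAGE_CATEGORIES))
  expect_identical(is.na(cats$rank), cats$category == "NOT_EXPRESSED")
})

test_that("categories are invariant to gene order and per-gene scaling", {
  cfg <- synth_config(n_genes_per_archetype = 25L, seed = 14L)
  u <- generate_universe(cfg)
  d <- generate_counts(u$labels, cfg)
  prof <- aggregate_profiles(qc_filter(d, min_genes = 50))
  ref <- classify_stages(prof)

  perm <- sample(nrow(prof))
  shuffled <- prof[perm, ]
  res_perm <- classify_stages(shuffled)
  merged <- merge(ref, res_perm, by = "gene_id")
  expect_identical(merged$category.x, merged$category.y)

  # multiplying one gene's mean profile by a constant changes nothing
  scaled <- prof
  mean_cols <- paste0("mean_", GERMLINE_CELL_TYPES)
  scaled[3, mean_cols] <- scaled[3, mean_cols] * 11
  res_scaled <- classify_stages(scaled)
  expect_identical(res_scaled$category, ref$category)
})

test_that("percent-based variant reproduces mean-based categories on clean data", {
  # shallow depth so detection is not saturated: the percent-expressed
  # profile only carries stage information when low-program cell types
  # show dropout
  cfg <- synth_config(n_genes_per_archetype = 30L, noise_dispersion = 0,
                      depth_mean = 500, seed = 15L)
  u <- generate_universe(cfg)
  d <- generate_counts(u$labels, cfg)
  prof <- aggregate_profiles(qc_filter(d, min_genes = 50))
  both <- categorization_agreement(prof)
  expect_true(both$agreement >= 0 && both$agreement <= 1)
  # pct profiles are coarser than means; demand near-complete agreement on
  # noiseless data at the planted-rank level
  ranks_mean <- category_rank(both$mean$category)
  ranks_pct <- category_rank(both$pct$category)
  same <- (is.na(ranks_mean) & is.na(ranks_pct)) |
    (!is.na(ranks_mean) & !is.na(ranks_pct) & ranks_mean == ranks_pct)
  expect_gte(mean(same), 0.95)
  # all-zero pct gene stays NOT_EXPRESSED
  expect_true(all(both$pct$category[rowSums(profile_matrix(prof, "pct")) == 0]
                  == "NOT_EXPRESSED"))
})
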