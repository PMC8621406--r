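small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes_per_archetype = 10L, cells_per_type = 10L,
         depth_mean = 2000, pair_design = small_design(), seed = 42L),
    list(...))
  do.call(synth_config, args)
}

test_that("universe has the requested size, chromosomes and labels", {
  u <- generate_universe(small_cfg())
  expect_equal(nrow(u$annotations), 60)
  expect_equal(nrow(u$labels), 60)
  expect_equal(as.vector(table(u$labels$archetype)[STAGE_CATEGORIES]),
               rep(10, 6))
  expect_true(all(u$annotations$chromosome %in% CHROMOSOMES))

  onehot <- c("2L" = 0, "2R" = 0, "3L" = 0, "3R" = 0, "4" = 0, X = 1, Y = 0)
  ux <- generate_universe(small_cfg(chrom_props = onehot))
  expect_true(all(ux$annotations$chromosome == "X"))
})

test_that("identical seed and config reproduce identical outputs", {
  cfg <- small_cfg(n_genes_per_archetype = 40L)
  a <- generate_universe(cfg)
  b <- generate_universe(cfg)
  expect_identical(a, b)
  pa <- generate_pairs(a, cfg)
  pb <- generate_pairs(b, cfg)
  expect_identical(pa, pb)
  ca <- generate_counts(pa$labels, cfg)
  cb <- generate_counts(pb$labels, cfg)
  expect_identical(as.matrix(ca$counts), as.matrix(cb$counts))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(chrom_props = c("2L" = 0.5, "2R" = 0.6,
                                            "3L" = 0, "3R" = 0, "4" = 0,
                                            X = 0, Y = 0)), "sum")
  expect_error(synth_config(noise_dispersion = -1), ">= 0")
  expect_error(synth_config(n_genes_per_archetype = -5), ">= 0")
  cfg <- small_cfg()
  cfg$cells_per_type <- 0L
  u <- generate_universe(cfg)
  expect_error(generate_counts(u$labels, cfg), "cells_per_type")
})

test_that("counts follow the planted programs", {
  cfg <- small_cfg(noise_dispersion = 0, depth_mean = 1e5)
  u <- generate_universe(cfg)
  d <- generate_counts(u$labels, cfg)
  expect_s4_class(d$counts, "Matrix")

  # NOT_EXPRESSED genes give all-zero columns
  off <- u$labels$gene_id[u$labels$archetype == "NOT_EXPRESSED"]
  expect_true(all(Matrix::colSums(d$counts[, off, drop = FALSE]) == 0))

  # in the near-noiseless deep limit, per-cell-type mean counts respect
  # every strict ordering in the archetype program
  programs <- archetype_programs()
  for (arch in setdiff(STAGE_CATEGORIES, "NOT_EXPRESSED")) {
    genes <- u$labels$gene_id[u$labels$archetype == arch]
    means <- vapply(GERMLINE_CELL_TYPES, function(ct)
      mean(as.matrix(d$counts[d$cell_types == ct, genes])), numeric(1))
    prog <- programs[arch, ]
    for (i in 1:3) for (j in (i + 1):4)
      if (prog[i] != prog[j])
        expect_equal(means[i] > means[j], prog[i] > prog[j],
                     info = paste(arch, i, j))
  }
})

test_that("aggregated counts recover the planted peak cell types", {
  cfg <- synth_config(seed = 5L)  # default: 600 genes, default noise
  u <- generate_universe(cfg)
  d <- generate_counts(u$labels, cfg)
  prof <- aggregate_profiles(qc_filter(d))
  m <- profile_matrix(prof, "mean")
  programs <- archetype_programs()
  arch <- setNames(u$labels$archetype, u$labels$gene_id)[rownames(m)]
  expressed <- arch != "NOT_EXPRESSED"
  hit <- vapply(which(expressed), function(i) {
    peaks <- which(programs[arch[i], ] == max(programs[arch[i], ]))
    which.max(m[i, ]) %in% peaks
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("pair planting honours the per-stratum shift probability", {
  # forced shift: every child planted at a meiotic rank above its parent
  design1 <- data.frame(route = "X_to_A", mechanism = "RNA", n_pairs = 20L,
                        p_into_meiosis = 1)
  xheavy <- c("2L" = 0.14, "2R" = 0.14, "3L" = 0.14, "3R" = 0.14,
              "4" = 0.02, X = 0.40, Y = 0.02)
  cfg1 <- synth_config(n_genes_per_archetype = 40L, cells_per_type = 5L,
                       chrom_props = xheavy, pair_design = design1, seed = 3L)
  pl1 <- generate_pairs(generate_universe(cfg1), cfg1)
  expect_true(all(pl1$pairs$planted_child_rank >= 3))
  expect_true(all(pl1$pairs$planted_parent_rank <= 2))
  expect_true(all(pl1$pairs$planted_child_rank >
                    pl1$pairs$planted_parent_rank))

  # no planting anywhere: the planted shift distribution is exactly zero
  design0 <- default_pair_design()
  design0$p_into_meiosis[design0$mechanism != "DENOVO"] <- 0
  cfg0 <- synth_config(n_genes_per_archetype = 120L, cells_per_type = 5L,
                       pair_design = design0, seed = 4L)
  pl0 <- generate_pairs(generate_universe(cfg0), cfg0)
  dup <- pl0$pairs[pl0$pairs$route != "de_novo", ]
  expect_true(all(dup$planted_child_rank == dup$planted_parent_rank))
})

test_that("pair routes are consistent with the annotated chromosomes", {
  cfg <- synth_config(seed = 9L)
  u <- generate_universe(cfg)
  pl <- generate_pairs(u, cfg)
  chrom <- setNames(u$annotations$chromosome, u$annotations$gene_id)
  derived <- derive_route(unname(chrom[pl$pairs$parent_id]),
                          unname(chrom[pl$pairs$child_id]))
  expect_identical(derived, pl$pairs$route)
  # X_to_A exactly when parent on X and child on a major autosome
  is_xa <- !is.na(pl$pairs$parent_id) &
    chrom[pl$pairs$parent_id] == "X" & chrom[pl$pairs$child_id] %in% AUTOSOMES
  expect_identical(unname(is_xa), pl$pairs$route == "X_to_A")
  # no gene serves as both parent and child
  expect_equal(anyDuplicated(c(pl$pairs$child_id,
                               na.omit(pl$pairs$parent_id))), 0L)
})

test_that("infeasible pair requests fail naming the stratum", {
  design <- data.frame(route = "X_to_A", mechanism = "RNA", n_pairs = 500L,
                       p_into_meiosis = 0.5)
  cfg <- synth_config(n_genes_per_archetype = 10L, cells_per_type = 5L,
                      pair_design = design, seed = 1L)
  expect_error(generate_pairs(generate_universe(cfg), cfg),
               "X_to_A, RNA")
})

test_that("recovery does not improve as dispersion grows", {
  # QC relaxed so that even heavily overdispersed cells survive to be scored
  rec <- vapply(c(0.3, 10, 60), function(disp) {
    rank_recovery(run_pipeline(synth_config(noise_dispersion = disp,
                                            seed = 11L), min_genes = 20L))
  }, numeric(1))
  expect_gte(rec[1], rec[2])
  expect_gte(rec[2], rec[3])
})
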