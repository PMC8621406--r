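#' Archetype expression programs
#'
#' Relative mean expression of each stage archetype over the four germline
#' cell types (spermatogonia, early spermatocytes, late spermatocytes,
#' spermatids). Each program peaks exactly on the cell types its category is
#' named after; only the rank structure matters downstream because profiles
#' are row-scaled before clustering. `NOT_EXPRESSED` is the zero program.
#'
#' @return numeric matrix, archetypes x 4 cell types.
#' @export
archetype_programs <- function() {
  m <- rbind(
    NOT_EXPRESSED       = c(0,    0,    0,    0),
    MITOSIS             = c(1,    0.10, 0.05, 0.05),
    MITOSIS_MEIOSIS     = c(1,    1,    0.10, 0.05),
    MEIOSIS             = c(0.10, 1,    1,    0.10),
    MEIOSIS_POSTMEIOSIS = c(0.05, 0.10, 1,    1),
    POSTMEIOSIS         = c(0.05, 0.05, 0.10, 1)
  )
  colnames(m) <- GERMLINE_CELL_TYPES
  m
}

#' Default pair design: strata and planted into-the-meiosis probabilities
#'
#' One row per (route, mechanism) stratum of parent/new-gene pairs to
#' simulate. `p_into_meiosis` is the probability that the new gene is planted
#' at a meiotic stage rank strictly above a mitotic parent; the default plants
#' a stronger shift for X-to-autosome retrogenes (0.6) than the 0.3
#' background, the signature expected if meiotic sex chromosome inactivation
#' pushes retrogenes off the X.
#'
#' @return data.frame with columns route, mechanism, n_pairs, p_into_meiosis.
#' @export
default_pair_design <- function() {
  data.frame(
    route = c("A_to_A_intra", "A_to_A_inter", "A_to_X", "X_to_A",
              "A_to_A_inter", "A_to_X", "X_to_A", "X_to_X",
              "de_novo"),
    mechanism = c("DNA", "DNA", "DNA", "DNA",
                  "RNA", "RNA", "RNA", "RNA",
                  "DENOVO"),
    n_pairs = c(60L, 20L, 5L, 8L, 9L, 3L, 6L, 2L, 28L),
    p_into_meiosis = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.6, 0.3, NA),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic spermatogenesis data generator
#'
#' @param n_genes_per_archetype genes simulated per archetype (6 archetypes:
#'   the 5 expressed stage programs plus `NOT_EXPRESSED`).
#' @param cells_per_type cells simulated per germline cell type.
#' @param depth_mean mean library size (total counts per cell).
#' @param noise_dispersion negative-binomial dispersion (>= 0); 0 gives
#'   Poisson counts.
#' @param chrom_props probability vector over [CHROMOSOMES]; must sum to 1.
#'   The default approximates the share of annotated D. melanogaster genes
#'   per chromosome arm.
#' @param pair_design data.frame as [default_pair_design()]: pairs per
#'   (route, mechanism) stratum and per-stratum planted shift probability.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes_per_archetype = 100L,
                         cells_per_type = 50L,
                         depth_mean = 5000,
                         noise_dispersion = 0.3,
                         chrom_props = c("2L" = 0.19, "2R" = 0.21,
                                         "3L" = 0.20, "3R" = 0.22,
                                         "4" = 0.01, "X" = 0.16, "Y" = 0.01),
                         pair_design = default_pair_design(),
                         seed = 1L) {
  if (n_genes_per_archetype < 0 || cells_per_type < 0)
    stop("counts must be >= 0")
  if (noise_dispersion < 0) stop("noise_dispersion must be >= 0")
  if (!setequal(names(chrom_props), CHROMOSOMES))
    stop("chrom_props must be named by the chromosomes ",
         paste(CHROMOSOMES, collapse = ", "))
  chrom_props <- chrom_props[CHROMOSOMES]
  if (abs(sum(chrom_props) - 1) > 1e-9 || any(chrom_props < 0))
    stop("chrom_props must be a probability vector summing to 1")
  need <- c("route", "mechanism", "n_pairs", "p_into_meiosis")
  if (!all(need %in% names(pair_design)))
    stop("pair_design must have columns ", paste(need, collapse = ", "))
  if (any(pair_design$n_pairs < 0)) stop("counts must be >= 0")
  structure(list(n_genes_per_archetype = as.integer(n_genes_per_archetype),
                 cells_per_type = as.integer(cells_per_type),
                 depth_mean = depth_mean,
                 noise_dispersion = noise_dispersion,
                 chrom_props = chrom_props,
                 pair_design = pair_design,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate the synthetic gene universe
#'
#' Draws one annotation row per gene: a chromosome from `chrom_props`, a
#' plausible gene length and exon count, and a true stage archetype (equal
#' numbers of genes per archetype). The true labels are returned so that
#' downstream recovery tests can compare classifications against the planted
#' truth.
#'
#' @param config a [synth_config()].
#' @return list with `annotations` (data.frame: gene_id, chromosome, length,
#'   exon_count) and `labels` (data.frame: gene_id, archetype).
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_arch <- length(STAGE_CATEGORIES)
  n <- config$n_genes_per_archetype * n_arch
  gene_id <- sprintf("g%05d", seq_len(n))
  archetype <- rep(STAGE_CATEGORIES, each = config$n_genes_per_archetype)
  # shuffle so archetype is independent of gene order
  ord <- sample.int(n)
  archetype <- archetype[ord]
  chromosome <- sample(CHROMOSOMES, n, replace = TRUE,
                       prob = config$chrom_props)
  annotations <- data.frame(
    gene_id = gene_id,
    chromosome = chromosome,
    length = pmax(200L, as.integer(round(stats::rlnorm(n, log(3000), 0.6)))),
    exon_count = 1L + stats::rpois(n, 3),
    stringsAsFactors = FALSE
  )
  labels <- data.frame(gene_id = gene_id, archetype = archetype,
                       stringsAsFactors = FALSE)
  list(annotations = annotations, labels = labels)
}

#' Generate a labeled cell-by-gene count matrix from archetype labels
#'
#' Each cell's expected expression of a gene is its archetype program value
#' at the cell's type, rescaled so the cell's expected library size equals
#' `depth_mean`. Counts are negative-binomial around that mean (Poisson at
#' dispersion 0). `NOT_EXPRESSED` genes yield all-zero columns.
#'
#' @param labels data.frame (gene_id, archetype) from [generate_universe()]
#'   (possibly re-planted by [generate_pairs()]).
#' @param config a [synth_config()].
#' @return a [labeled_counts()] object (sparse cell x gene matrix plus
#'   cell-type labels).
#' @export
generate_counts <- function(labels, config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$cells_per_type < 1) stop("cells_per_type must be >= 1")
  set.seed(config$seed + 1L)
  programs <- archetype_programs()
  prog <- programs[labels$archetype, , drop = FALSE]  # gene x cell type
  n_genes <- nrow(labels)
  n_cells <- config$cells_per_type * length(GERMLINE_CELL_TYPES)
  cell_type <- rep(GERMLINE_CELL_TYPES, each = config$cells_per_type)
  cell_id <- sprintf("%s_c%04d", cell_type, seq_len(n_cells))
  counts <- matrix(0L, nrow = n_cells, ncol = n_genes,
                   dimnames = list(cell_id, labels$gene_id))
  size <- if (config$noise_dispersion > 0) 1 / config$noise_dispersion else Inf
  for (ct in GERMLINE_CELL_TYPES) {
    w <- prog[, ct]
    tot <- sum(w)
    if (tot <= 0)
      stop("all archetype programs are zero in cell type ", ct)
    mu <- config$depth_mean * w / tot
    rows <- which(cell_type == ct)
    for (i in rows) {
      counts[i, ] <- if (is.finite(size))
        stats::rnbinom(n_genes, mu = mu, size = size)
      else
        stats::rpois(n_genes, lambda = mu)
    }
  }
  labeled_counts(Matrix::Matrix(counts, sparse = TRUE),
                 data.frame(cell_id = cell_id, cell_type = cell_type,
                            stringsAsFactors = FALSE))
}

.route_chroms <- function(route) {
  A <- AUTOSOMES
  switch(route,
         A_to_A_intra = list(parent = A, child = A, intra = TRUE),
         A_to_A_inter = list(parent = A, child = A, intra = FALSE),
         A_to_X       = list(parent = A, child = "X", intra = FALSE),
         X_to_A       = list(parent = "X", child = A, intra = FALSE),
         X_to_X       = list(parent = "X", child = "X", intra = TRUE),
         de_novo      = list(parent = NULL, child = c(A, "X"), intra = FALSE),
         stop("unknown route: ", route))
}

#' Generate parent/new-gene pairs with planted stage shifts
#'
#' For each (route, mechanism) stratum of the design, parents and children
#' are sampled from genes on the chromosomes the route requires. With the
#' stratum's `p_into_meiosis` probability a pair is planted as an
#' into-the-meiosis shift: the parent is drawn from mitotic-stage genes
#' (rank 1 or 2) and the child's archetype is re-planted at a meiotic stage
#' rank (3 or 4); otherwise the child is re-planted at its parent's rank, so
#' the unplanted shift is exactly 0. De novo children keep their own
#' archetype and have no parent. Children are sampled without replacement;
#' an infeasible stratum raises an error naming it.
#'
#' @param universe list from [generate_universe()].
#' @param config a [synth_config()].
#' @return list with `pairs` (data.frame: child_id, parent_id, branch,
#'   mechanism, route, planted_parent_rank, planted_child_rank) and `labels`,
#'   the universe labels with children re-planted. Pass these labels to
#'   [generate_counts()].
#' @export
generate_pairs <- function(universe, config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  annotations <- universe$annotations
  labels <- universe$labels
  design <- config$pair_design
  arch <- setNames(labels$archetype, labels$gene_id)
  chrom <- setNames(annotations$chromosome, annotations$gene_id)
  rank_of <- setNames(category_rank(labels$archetype), labels$gene_id)
  # genes already committed as a parent or child: a gene plays one role only,
  # so re-planting a child can never invalidate an earlier pair's parent rank
  used <- character(0)
  out <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    route <- design$route[s]
    mech <- design$mechanism[s]
    n <- design$n_pairs[s]
    p <- design$p_into_meiosis[s]
    rc <- .route_chroms(route)
    stratum <- paste0("(", route, ", ", mech, ")")
    if (n == 0) { out[[s]] <- NULL; next }
    child_pool <- names(arch)[chrom[names(arch)] %in% rc$child &
                              arch != "NOT_EXPRESSED" &
                              !names(arch) %in% used]
    if (length(child_pool) < n)
      stop("cannot sample ", n, " children for stratum ", stratum,
           ": only ", length(child_pool), " eligible genes")
    children <- sample(child_pool, n)
    used <- c(used, children)
    if (route == "de_novo") {
      out[[s]] <- data.frame(
        child_id = children, parent_id = NA_character_,
        branch = sample(1:6, n, replace = TRUE),
        mechanism = mech, route = route,
        planted_parent_rank = NA_integer_,
        planted_child_rank = unname(rank_of[children]),
        stringsAsFactors = FALSE)
      next
    }
    planted <- stats::runif(n) < p
    base_pool <- names(arch)[chrom[names(arch)] %in% rc$parent &
                             arch != "NOT_EXPRESSED" &
                             !names(arch) %in% used]
    parents <- character(n)
    for (i in seq_len(n)) {
      pool <- setdiff(base_pool, parents)
      if (planted[i]) pool <- pool[rank_of[pool] <= 2]
      if (route == "A_to_A_intra")
        pool <- pool[chrom[pool] == chrom[children[i]]]
      if (route == "A_to_A_inter")
        pool <- pool[chrom[pool] != chrom[children[i]]]
      if (!length(pool))
        stop("cannot sample a ", if (planted[i]) "mitotic " else "",
             "parent for stratum ", stratum)
      parents[i] <- if (length(pool) == 1) pool else sample(pool, 1)
    }
    used <- c(used, parents)
    parent_rank <- unname(rank_of[parents])
    child_rank <- integer(n)
    child_rank[planted] <- sample(3:4, sum(planted), replace = TRUE)
    child_rank[!planted] <- parent_rank[!planted]
    # re-plant child archetypes
    arch[children] <- rank_category(child_rank)
    rank_of[children] <- child_rank
    out[[s]] <- data.frame(
      child_id = children, parent_id = parents,
      branch = sample(1:6, n, replace = TRUE),
      mechanism = mech, route = route,
      planted_parent_rank = parent_rank,
      planted_child_rank = child_rank,
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  rownames(pairs) <- NULL
  labels$archetype <- unname(arch[labels$gene_id])
  list(pairs = pairs, labels = labels)
}
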