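#' Run the full analysis pipeline
#'
#' End-to-end orchestration: synthetic data generation (or user-supplied
#' tables), QC and pseudobulk aggregation, stage classification, chromosomal
#' enrichment, parent/new-gene shift analysis, and the out-of-the-X traffic
#' test. Genes removed by QC or silent in all germline cell types are carried
#' as `NOT_EXPRESSED` so category counts conserve the input gene total. A
#' manifest records the seed, the parameters, and record counts at every
#' step.
#'
#' @param config a [synth_config()]; alternatively supply `data`, `pairs`
#'   and `annotations` directly to run on real inputs.
#' @param data optional [labeled_counts()] (bypasses the generator).
#' @param pairs optional pair table (child_id, parent_id, branch, mechanism).
#' @param annotations optional annotation table (gene_id, chromosome, ...).
#' @param chrom_lengths named vector of chromosome lengths in bp for the
#'   traffic null; defaults to the D. melanogaster r6 arm lengths.
#' @param k,theta stage-classifier parameters, see [classify_stages()].
#' @param min_cells,min_genes QC thresholds, see [qc_filter()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV and the manifest as JSON.
#' @return list: profile, categories, counts_by_chrom, enrichment, ratios,
#'   shift_records, spectrum, composition, nonoverlap, traffic, manifest
#'   (and, for synthetic runs, the generated truth: labels, pairs,
#'   annotations).
#' @export
run_pipeline <- function(config = synth_config(), data = NULL, pairs = NULL,
                         annotations = NULL,
                         chrom_lengths = c("2L" = 23513712, "2R" = 25286936,
                                           "3L" = 28110227, "3R" = 32079331,
                                           "4" = 1348131, "X" = 23542271,
                                           "Y" = 3667352),
                         k = 7L, theta = 0,
                         min_cells = 3L, min_genes = 200L,
                         out_dir = NULL) {
  manifest <- list(seed = config$seed, k = k, theta = theta,
                   min_cells = min_cells, min_genes = min_genes)
  truth <- NULL
  if (is.null(data)) {
    universe <- generate_universe(config)
    planted <- generate_pairs(universe, config)
    annotations <- universe$annotations
    pairs <- planted$pairs
    data <- generate_counts(planted$labels, config)
    truth <- list(labels = planted$labels, pairs = pairs,
                  annotations = annotations)
    manifest$synthetic <- TRUE
    manifest$n_genes_simulated <- nrow(annotations)
  } else if (is.null(annotations)) {
    stop("annotations are required when supplying real data")
  }
  manifest$n_cells_in <- nrow(data$counts)
  manifest$n_genes_in <- ncol(data$counts)
  all_genes <- colnames(data$counts)

  filtered <- qc_filter(data, min_cells = min_cells, min_genes = min_genes)
  manifest$n_cells_qc <- nrow(filtered$counts)
  manifest$n_genes_qc <- ncol(filtered$counts)
  manifest$genes_dropped_qc <- setdiff(all_genes, colnames(filtered$counts))

  profile <- aggregate_profiles(filtered)
  categories <- classify_stages(profile, k = k, mode = "mean", theta = theta)
  # genes dropped by QC were detected in <3 cells: not expressed
  dropped <- setdiff(all_genes, categories$gene_id)
  if (length(dropped))
    categories <- rbind(categories,
                        data.frame(gene_id = dropped,
                                   category = "NOT_EXPRESSED",
                                   rank = NA_integer_,
                                   cluster = NA_integer_,
                                   stringsAsFactors = FALSE))
  manifest$category_counts <-
    as.list(table(factor(categories$category, levels = STAGE_CATEGORIES)))

  counts_by_chrom <- count_by_chrom(categories, annotations)
  enrichment <- enrichment_table(counts_by_chrom)
  ratios <- do.call(rbind, lapply(
    setdiff(CHROMOSOMES, AUTOSOMES), function(ch) {
      cats <- setdiff(STAGE_CATEGORIES, "NOT_EXPRESSED")
      data.frame(chromosome = ch, category = cats,
                 ratio = vapply(cats, function(ca)
                   normalized_ratio(counts_by_chrom, ch, ca), numeric(1)),
                 stringsAsFactors = FALSE)
    }))

  shift_records <- spectrum <- composition <- nonoverlap <- traffic <- NULL
  if (!is.null(pairs) && nrow(pairs)) {
    shift_records <- build_shift_records(pairs, categories, annotations)
    spectrum <- shift_spectrum(shift_records)
    nonoverlap <- nonoverlap_fraction(shift_records, by = "branch")
    dup <- shift_records[shift_records$route != "de_novo", ]
    composition <- do.call(rbind, lapply(
      split(dup, paste(dup$route, dup$mechanism, sep = ":")), function(d) {
        ok <- !is.na(d$child_category) & !is.na(d$parent_category)
        d <- d[ok, ]
        if (!nrow(d) ||
            all(d$child_category == "NOT_EXPRESSED") ||
            all(d$parent_category == "NOT_EXPRESSED")) return(NULL)
        composition_compare(d$child_category, d$parent_category,
                            stratum = paste(d$route[1], d$mechanism[1],
                                            sep = ":"))
      }))
    denovo <- shift_records[shift_records$route == "de_novo", ]
    if (nrow(denovo) &&
        any(denovo$child_category != "NOT_EXPRESSED", na.rm = TRUE)) {
      bg <- categories$category
      composition <- rbind(composition,
                           composition_compare(denovo$child_category, bg,
                                               stratum = "de_novo:background"))
    }
    rownames(composition) <- NULL
    # out-of-the-X test on inter-chromosomal retrogene movements
    rna <- pairs[pairs$mechanism == "RNA" & !is.na(pairs$parent_id), ]
    if (nrow(rna)) {
      obs <- observed_traffic(rna, annotations)
      g <- setNames(as.numeric(table(factor(annotations$chromosome,
                                            levels = CHROMOSOMES))),
                    CHROMOSOMES)
      exp_m <- expected_traffic(sum(obs), g, chrom_lengths[CHROMOSOMES],
                                exclude_intra = TRUE)
      traffic <- tryCatch(out_of_x_test(obs, exp_m),
                          error = function(e) {
                            warning("traffic test skipped: ",
                                    conditionMessage(e))
                            NULL
                          })
    }
  }
  manifest$n_pairs <- if (is.null(pairs)) 0L else nrow(pairs)

  result <- list(profile = profile, categories = categories,
                 counts_by_chrom = counts_by_chrom,
                 enrichment = enrichment, ratios = ratios,
                 shift_records = shift_records, spectrum = spectrum,
                 composition = composition, nonoverlap = nonoverlap,
                 traffic = traffic, manifest = manifest, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(profile, file.path(out_dir, "profile.tsv"))
    write_tsv(categories, file.path(out_dir, "categories.tsv"))
    write_tsv(as.data.frame.table(counts_by_chrom,
                                  responseName = "n_genes"),
              file.path(out_dir, "counts_by_chrom.tsv"))
    write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_tsv(ratios, file.path(out_dir, "ratios.tsv"))
    if (!is.null(shift_records)) {
      write_tsv(shift_records, file.path(out_dir, "shift_records.tsv"))
      write_tsv(spectrum, file.path(out_dir, "shift_spectrum.tsv"))
      if (!is.null(composition))
        write_tsv(composition, file.path(out_dir, "composition.tsv"))
    }
    if (!is.null(traffic))
      write_tsv(traffic$classes, file.path(out_dir, "traffic_classes.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
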