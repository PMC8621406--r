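---
title: "Methods: stage classification and chromosomal traffic of new genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage classification and chromosomal traffic of new genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagetraffic)
```

## The problem

During *Drosophila* spermatogenesis, germ cells progress from mitotically
dividing spermatogonia through early and late primary spermatocytes
(meiosis) to haploid spermatids. The X chromosome is transcriptionally
silenced in spermatocytes (meiotic sex chromosome inactivation, MSCI), which
is thought to push young genes — especially retrogenes, whose new insertion
site severs them from their parental regulatory context — off the X and onto
autosomes, where they can be expressed in meiotic and post-meiotic cells.

`stagetraffic` implements the cell-level analysis chain for this question:
it turns a labeled single-cell count matrix into per-gene stage profiles,
assigns each gene a spermatogenesis stage category, quantifies how stage
categories distribute over chromosomes, scores the stage shift between
parental and new gene copies, and tests whether retrogene movement out of
the X exceeds a neutral expectation. A synthetic-data generator with planted
truth makes every stage of the chain testable end to end.

## Pseudobulk stage profiles

The pipeline starts from a cell × gene count matrix whose cells are already
annotated with one of the four germline cell types; upstream processing
(alignment, doublet removal, integration, clustering, marker-based
annotation) is out of scope. Two quality filters are applied: genes detected
(count > 0) in fewer than 3 cells and cells detecting fewer than 200 genes
are removed. Both masks are computed on the input matrix and applied in one
joint pass — iterating the two filters to a fixed point changes little in
practice but is available via `qc_filter(iterate = TRUE)`. "Detected" means
at least one count; no higher threshold is imposed.

Each cell is then normalized to counts per million (CPM, over the post-QC
gene set), and each gene is summarized per cell type by

* `mean_expr`: the mean of log2(CPM + 1) over that type's cells, and
* `pct_expr`: the percentage of that type's cells detecting the gene.

Both summaries are invariant to cell order and to rescaling any cell's
depth by a constant. A gene whose four `mean_expr` values are all zero is
categorized `NOT_EXPRESSED` and excluded from clustering; genes dropped by
the gene filter are carried through the pipeline under the same label so
that category counts always conserve the input gene total.

## Stage categories by hierarchical clustering

Expressed genes are classified by unsupervised clustering of their 4-vector
profiles:

1. each row is z-scaled (mean 0, sample SD 1; constant rows map to zeros),
   so only profile shape matters;
2. complete-linkage agglomerative clustering on Euclidean distances builds a
   dendrogram, which is cut into `k = 7` clusters;
3. each cluster's centroid (mean scaled profile) defines its *enriched set*:
   the cell types with centroid value above `theta = 0`, i.e. above the
   gene's own mean;
4. the enriched set maps to a category: {spermatogonia} → `MITOSIS`;
   {spermatogonia, early spermatocytes} → `MITOSIS_MEIOSIS`; any subset of
   the spermatocyte types → `MEIOSIS`; {late spermatocytes, spermatids} →
   `MEIOSIS_POSTMEIOSIS`; {spermatids} → `POSTMEIOSIS`.

The distance metric is a genuine free choice — the linkage is fixed by the
method but the metric is not stated with it — and Euclidean on scaled rows
is the default of the heatmap tooling this procedure descends from; it is
exposed should anyone want correlation distances instead. The 7 → 5 merging
rule above is an operationalization of "divide clusters by expression
pattern": a cluster whose enriched set is empty falls back to the centroid's
argmax cell type, and a non-contiguous or 3+-type set falls back to the
recognized set with the highest mean centroid mass; both fallbacks are
flagged in the output because they indicate clusters without a clean stage
identity. Determinism across platforms is obtained by sorting genes by id
before clustering, which fixes the tie order in `hclust`'s merge sequence.

For downstream scoring the four expressed categories are ranked 1–4 along
development. `POSTMEIOSIS` shares rank 4 with `MEIOSIS_POSTMEIOSIS`: the
post-meiotic cluster holds few genes and all downstream tests pool the
meiotic and post-meiotic stages.

A robustness variant, `classify_stages(mode = "pct")`, runs the identical
pipeline on the percent-expressed profiles. Note that `pct_expr` saturates
at 100% in deeply sequenced data; the variant is informative only when
dropout leaves a detection gradient across cell types.

## Chromosomal enrichment

`count_by_chrom()` tabulates genes by chromosome arm × category (dense:
absent combinations are zeros). Each non-reference chromosome (X, Y, and
the dot chromosome 4) is compared against the pooled major autosome arms
(2L, 2R, 3L, 3R) with a two-sided Fisher exact test per category; the
meiotic categories are pooled for testing. The "normalized ratio" for
chromosome C and category s is
$(n_{s,C}/n_C)\,/\,(n_{s,A}/n_A)$ — the category's prevalence on C relative
to the autosomes, 1 meaning parity. Significance flags follow the raw
Fisher p (as in the conventional presentation of such tables), but
Benjamini–Hochberg q-values over the family of tests are always reported
alongside.

## Parent–new gene stage shifts

For a pair with both genes expressed, the stage shift is
`child_rank − parent_rank` ∈ −3..3. The direction taxonomy partitions the
16 rank pairs: crossing the mitotic/meiotic boundary (ranks {1,2} vs {3,4})
upward is `INTO_MEIOSIS`, downward `INTO_MITOSIS`; same-side pairs are
`WITHIN_MITOTIC` or `WITHIN_MEIOTIC`. The two verbal definitions this
taxonomy descends from overlap (a 1 → 2 change is "positive for a mitotic
parent" but also "differs by 1 or less"); requiring a boundary crossing for
the INTO classes makes the taxonomy a true partition while keeping the
worked example — parent rank 1, child rank 4, shift +3 — an
`INTO_MEIOSIS` change. Pairs with an unexpressed member are excluded from
shift statistics but counted per stratum as unclassified.

Composition comparisons (`composition_compare()`) run per-category Fisher
tests between children and parents within each (route, mechanism) stratum,
and between de novo genes and the genomic background — defined as all
categorized genes in the annotation table. The non-overlap fraction of a
stratum is the share of expressed pairs whose categories' cell-type sets
are disjoint (e.g. {spermatogonia} vs {spermatids}).

## Out-of-the-X traffic

Under the null, the number of pairs moving i → j is proportional to the
source chromosome's share of parental genes and the target chromosome's
share of genomic sequence: $E[i \to j] = N (g_i/\sum g)(L_j/\sum L)$.
Because retroposition is analyzed as an inter-chromosomal process, the
diagonal is zeroed and each row renormalized so row totals are preserved
(`exclude_intra = TRUE`). The observed and expected matrices are collapsed
into classes — by default X-source vs autosome-source movements, the
"out of the X" contrast — and compared with a plain Pearson chi-square,
$\sum (O-E)^2/E$, df = classes − 1, without continuity correction. The
length-proportional insertion null can be replaced by an empirical target
frequency vector through the `L` argument. Expected class counts below 1
trigger an unreliability warning rather than an error.

## The synthetic-data generator

The generator emulates the shape of the study's inputs, not their content:

* **Archetypes.** Each gene carries one of five stage programs (or is
  `NOT_EXPRESSED`). Programs are fixed template vectors over the four cell
  types (e.g. mitosis = (1, 0.1, 0.05, 0.05)) that peak exactly on the cell
  types of their category; only their rank structure matters downstream
  because profiles are row-scaled.
* **Counts.** A cell of type t expects `depth_mean` total counts split
  across genes proportionally to their program value at t; counts are
  negative-binomial with dispersion `noise_dispersion` (Poisson at 0). Any
  overdispersed count model would do for testing the pipeline; NB is the
  standard realistic choice for UMI data.
* **Chromosomes.** Drawn i.i.d. from `chrom_props`, which defaults to the
  approximate share of annotated genes per *D. melanogaster* arm.
* **Pairs.** Each (route, mechanism) stratum requests `n_pairs` pairs. With
  probability `p_into_meiosis` a pair is planted as an into-the-meiosis
  shift: the parent is drawn from mitotic-stage genes (rank 1–2) and the
  child re-planted at a meiotic rank (3–4); otherwise the child is
  re-planted at its parent's rank, so the unplanted shift is exactly zero.
  This makes the stratum's expected `INTO_MEIOSIS` fraction equal
  `p_into_meiosis` up to classification noise — the cleanest way to make a
  planted effect size testable. A gene serves as parent or child at most
  once, so re-planting can never retroactively change an earlier pair. De
  novo children keep their own archetype and have no parent. The default
  plants a 0.6 probability for X→A retrogenes against a 0.3 background —
  there is no quantitative effect size to inherit for this contrast, so the
  defaults are deliberate, visible configuration, and the package's tests
  verify detection of precisely this planted contrast.

Each generator stage seeds the RNG from `seed` plus a fixed offset, so a
config reproduces its outputs byte-identically, composably across stages.

What the generator does *not* emulate: ambient RNA, doublets, batch
structure between strains, cell-type misannotation, gene-length or GC
biases, and any correlation between chromosome and expression program
beyond what `chrom_props` and pair planting induce. Passing recovery tests
on synthetic data therefore shows the pipeline recovers planted structure
through realistic count noise — not that the biological claims would
replicate on arbitrary real data.

## Default parameters and problem sizes

| parameter | default | meaning |
|---|---|---|
| `n_genes_per_archetype` | 100 | 600 genes total, 500 expressed |
| `cells_per_type` | 50 | 200 cells; pseudobulk means average 50 cells |
| `depth_mean` | 5000 | shallow droplet-style libraries |
| `noise_dispersion` | 0.3 | typical UMI overdispersion |
| `k` | 7 | dendrogram cut, merged to 5 categories |
| `theta` | 0 | centroid enrichment threshold (above own mean) |
| `min_cells`, `min_genes` | 3, 200 | QC thresholds |

The test suite runs the full pipeline at 600 genes × 200 cells (where
planted stage ranks are recovered for ≥95% of expressed genes at default
noise) and a 50-replicate detection study at 2100 genes × 200 cells with
100 pairs in each of six inter-chromosomal strata. These sizes were chosen
as the smallest at which pseudobulk averaging makes recovery reliable and
the planted 0.6-vs-0.3 contrast is overwhelmingly detectable; the whole
suite completes in well under a minute.

## Known limitations

* The 7-cluster cut cannot be compared cluster-by-cluster against any
  particular published heatmap — the merging rule, not cluster identities,
  is the contract.
* The enriched-set fallbacks (argmax, nearest contiguous set) are
  heuristics for clusters without a clean stage identity; they are flagged
  so users can inspect such clusters.
* Multiple input matrices are concatenated after per-cell CPM without batch
  correction (a warning is logged); integrating strains properly is
  upstream of this package.
* The traffic null treats insertions as length-proportional and
  independent; hotspots or insertion biases must be supplied as an
  empirical target-frequency vector.
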