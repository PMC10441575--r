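---
title: "Signature discovery and random-forest cell typing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery and random-forest cell typing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunosig)
```

## The problem

Cell-type annotation in scRNA-seq usually runs through cell-space clustering
plus marker inspection, or through reference-mapping tools that consume
thousands of highly variable genes (HVGs). Both approaches spend the
information in exactly the genes a downstream analysis wants to test, so
differential-expression p-values computed on cell groups defined from those
same genes are optimistic. `immunosig` takes the opposite route: it looks
for structure in the *gene* dimension — groups of genes whose expression
profiles across cells are mutually similar in several independent datasets —
and distills them into compact cell-type signatures. Classification then
needs only those few genes, leaving the rest of the transcriptome untouched
for unbiased statistics.

## Model and assumptions

The discovery model assumes that (i) a cell-type marker program manifests as
a set of genes with correlated profiles across cells *in every dataset*,
(ii) after per-dataset gene-wise Z-scaling (or external anchor-based
integration), those correlations survive concatenation of datasets, and
(iii) shared biological programs that are *not* cell types (interferon
response, cell cycle) also form correlated gene sets, but with weak
cell-type contrast — which is what the final filter exploits.

The pipeline (`discover_signatures()`):

1. **QC**: drop cells with < `min_genes_per_cell` (200) detected genes, then
   genes detected in < `min_cells_per_gene` (3) cells. The two filters do
   not commute; cells-first makes the gene filter deterministic given the
   retained cells and matches common practice.
2. **LogNormalize**: `ln(1 + s·c/C)` with scale factor `s = 10^4`, the cited
   method's default, exposed as a parameter.
3. **HVG selection** (`select_hvgs()`): per dataset, gene variance of
   log-normalized expression is standardized against the median variance of
   genes with similar mean (20 equal-count mean bins — a binned, smoother-free
   stand-in for a fitted mean–variance trend); genes are ranked per dataset
   and aggregated by median rank. Any ranking consistent with variance
   ordering is defensible; this one is robust to a single outlier dataset.
4. **Integration fallback** (`integrate_collection()`): per-dataset gene-wise
   Z-scaling on the common HVGs, then column concatenation. This removes
   additive per-dataset offsets on the log scale exactly (each dataset block
   has per-gene mean 0), which is precisely the batch structure the
   simulator generates; it does not correct nonlinear batch distortions,
   for which an externally integrated Z-scaled matrix should be supplied.
5. **Gene embedding** (`embed_genes()`): UMAP on gene rows, 2 components,
   `n_neighbors = 15`, `min_dist = 0.1`, seeded and single-threaded (hence
   deterministic). Profiles are first reduced to `pca = 20` principal
   components. The PCA step matters: on raw 10^3–10^4-dimensional Z-scaled
   profiles, a small module whose only correlation structure is internal
   (no attractive edges to any other structured module) is regularly torn
   apart by the layout and swallowed by the unstructured background cloud;
   after PCA denoising, planted modules embed as tight, well-separated
   clumps. Tests therefore assert locality properties of the embedding, not
   coordinates.
6. **DBSCAN** (`cluster_genes()`): canonical algorithm, Euclidean metric,
   closed neighborhoods (d ≤ ε) with the point counting toward its own
   neighborhood, noise label 0, cluster ids numbered by the first core point
   in input gene order, border points claimed by the first cluster reaching
   them in that deterministic order. Defaults ε = 0.18 (the reference
   workflow's tuned value) and minPts = 10.
7. **Epsilon selection**: three routes. (a) fixed ε; (b) `knee_epsilon()` —
   the Kneedle-style maximum perpendicular distance to the chord of the
   ascending k-NN distance curve, with `k` defaulting to minPts; (c)
   `dense_epsilon()` — a low quantile (default 0.1) of the same curve, such
   that roughly that fraction of genes qualify as core points.
   `discover_signatures()` defaults to (c): the global knee tracks the
   transition from the bulk of genes to outliers and routinely lands far
   above the scale of small dense modules, merging them with the background;
   picking a value *below* the knee for higher resolution is exactly how the
   reference workflow chose its final ε, and the dense quantile automates
   that choice. `epsilon_scan()` supports the manual grid-inspection route;
   final selection among candidates remains a user decision.
8. **Refinement** (`refine_gene_clusters()`), strictly in order: (I) remove
   genes with silhouette < 0; (II) remove clusters with < 10 remaining
   genes; (III) keep the top 50 genes per cluster by descending silhouette,
   ties broken by input gene order. Silhouettes are computed once, before
   filter I, on the correlation distance `1 − r` between Z-scaled profiles;
   they are not recomputed between filters. Noise genes are excluded from
   silhouette computation and all downstream filters; singleton clusters get
   silhouette 0 (the library convention) and are removed by filter II
   anyway. Applying the composed refinement to its own output changes
   nothing.
9. **Max-median filter** (`max_median_filter()`, filter IV): for each
   signature and dataset, the contrast between the maximum and the median
   per-cell-type mean score; a signature is removed when the contrast is
   < 0.6 (strict, in average Z-score units — no further transform is applied
   to the scores) in at least 3 datasets. A program spanning most cell types
   has its median near its maximum, so it fails this contrast even though it
   clusters perfectly well.
10. **Annotation and validation**: a signature is assigned to the cell type
    that is the score argmax in ≥ 3 datasets; if no type reaches the
    threshold, or two types tie for the maximal count, it stays unassigned —
    an arbitrary tie-break would silently mislabel. Validation is a
    one-sided (greater) Wilcoxon rank-sum test of per-cell scores in the
    assigned type vs all other cells, uncorrected p < 0.01 in ≥ 3 datasets;
    a Benjamini–Hochberg option exists but is off by default, matching the
    uncorrected rule the workflow was defined with.

## Classification

`train_classifier()` fits a random forest (500 trees, `floor(sqrt(p))`
features per split — the classical defaults) on the Z-scaled expression of
the genes shared among the signature set, the reference, and the query; the
67:33 split (`split_train_test()`) is simple random sampling, with an
optional stratified mode for tiny classes. Query features are Z-scaled with
the query's own per-gene statistics by default, mirroring per-dataset
Z-scaled matrices; `scaling = "train"` reuses the training statistics
instead — the choice matters when query cell-type composition differs
sharply from the reference, and both modes are exposed because neither is
canonical. Every cell receives a label; an optional `min_vote_share` cutoff
can reject low-confidence calls but is off by default. `evaluate()` computes
one-vs-rest accuracy, sensitivity, specificity, NPV, PPV and F1 per class;
ratios with zero denominators are set to 0 and flagged rather than
propagated as NaN, and reported "macro" values are unweighted means over
classes (the most common reading of a mean metric across classes; per-class
values are always available).

## What the simulator emulates — and what it does not

`simulation_design()` plants, in `n_datasets = 3` datasets of
`n_celltypes = 4` × `cells_per_type_per_dataset = 200` cells over
`n_genes = 300` genes: one 10-gene marker module per cell type
(`marker_effect = 1.5` natural-log units), one 10-gene program module active
in all datasets and all but one cell type (`program_effect = 1.5`),
per-dataset per-gene batch offsets (`batch_sd = 0.3`), lognormal library
sizes (log-mean `log(5000)`, log-sd 0.3) and negative-binomial counts
(`nb_dispersion = 2`). Expected counts are the library size times per-cell
normalized expression fractions proportional to
`exp(base + batch + marker + program)`; normalizing the fractions per cell
keeps column sums concentrated around the drawn library sizes. Counts are
independent per gene and cell given these means: module co-expression arises
entirely from shared mean shifts, which suffices to create gene-space
clusters. One RNG stream is keyed by `seed`, with per-dataset sub-seeds
drawn from it, so identical designs are bit-reproducible.

Two generator choices deserve note. The 300-gene universe stands in for the
post-HVG gene space at desk scale — what matters for the discovery geometry
is the *ratio* of structured to unstructured genes (50/300), not the
absolute count. And the program module deliberately spans all but one cell
type: a program elevated uniformly in *every* cell type has no cross-cell
variance after Z-scaling, is invisible to gene-space clustering, and could
never reach the max-median filter; sparing one type gives it the realistic
IFN-like structure — clusterable, but with median ≈ max across cell types —
that filter IV exists to reject.

The simulator does **not** model zero-inflation beyond NB sampling,
continuous/transitional cell states, nonlinear batch effects, doublets or
ambient RNA. Passing the recovery tests therefore shows the pipeline's
machinery is correct under its stated assumptions, not that it is robust to
every artifact of real data; on real collections, anchor-based integration
and inspection of the ε grid remain advisable.

## Numerical choices and degenerate inputs

- Z-scaling uses the sample standard deviation (n − 1); constant genes map
  to all-zero rows rather than NaN. Re-Z-scaling is the identity within
  1e-10 for non-constant genes.
- Rank-sum tests use the exact distribution for small untied samples and the
  tie-corrected normal approximation otherwise (the two agree within 0.01 at
  group sizes of 40 in the test suite); genes constant across both groups
  get p = 1. DGE in the bias comparison is two-sided; enrichment validation
  is one-sided greater.
- `knee_point()` on a numerically collinear curve returns the midpoint with
  a warning; an all-equal curve returns that constant.
- Signature genes absent from a matrix are dropped with a warning (scores
  average over present genes); a fully absent signature is an error listing
  the missing genes.
- Matrix-market files are 1-based as the format dictates; all internal
  indexing is R's.

## Problem sizes in the test suite

Unit tests run on 100–300-gene, 100–800-cell fixtures built in code; oracle
equivalence checks use 200 random DBSCAN instances of up to 500 points,
silhouette instances of up to 200 genes, and 1,000 random label vectors for
the metrics; end-to-end recovery and classification use the default
simulation design above; null calibration uses 7 effect-free datasets and
500 random signatures. The full suite and the acceptance script each run in
well under five minutes on one core.

## Known limitations

- The built-in integration removes only per-dataset location/scale
  differences; reciprocal-PCA-style anchor integration must come from
  external tooling.
- minPts = 10 means modules of fewer than ~10 genes cannot be discovered.
- The shipped medium-level PBMC label map is a reconstruction covering
  common vocabularies and should be overridden when a study's own
  harmonization table is available.
- Gene identity is exact symbol matching; no alias or ortholog resolution.
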