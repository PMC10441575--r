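#' Average Z-score of a gene signature per cell
#'
#' The signature score of a cell is the mean of its Z-scaled expression
#' values over the signature genes present in the matrix. Absent genes are
#' dropped with a warning; if none is present an error lists them.
#'
#' @param z Zscore-layer `ExpressionMatrix`.
#' @param genes Character vector of signature genes.
#' @return Named numeric vector of per-cell scores.
#' @export
mean_signature_score <- function(z, genes) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  if (z$layer != "zscore") stop("mean_signature_score expects a zscore-layer matrix")
  present <- intersect(genes, gene_ids(z))
  if (!length(present)) {
    stop("no signature gene present in matrix; missing: ",
         paste(genes, collapse = ", "))
  }
  absent <- setdiff(genes, present)
  if (length(absent)) {
    warning("dropping ", length(absent), " signature gene(s) absent from matrix: ",
            paste(utils::head(absent, 5), collapse = ", "))
  }
  colMeans(z$values[present, , drop = FALSE])
}

#' Score every signature of a set per cell
#'
#' @param z Zscore-layer `ExpressionMatrix`.
#' @param sig A `SignatureSet`.
#' @return Signatures x cells numeric matrix of mean Z-scores.
#' @export
score_signature_set <- function(z, sig) {
  stopifnot(inherits(sig, "SignatureSet"))
  t(vapply(sig$entries, function(g) mean_signature_score(z, g),
           numeric(ncol(z$values))))
}

#' Collapse per-cell signature scores to per-cell-type means
#'
#' @param scores Signatures x cells score matrix (columns named by cell id).
#' @param ann Cell annotation `data.frame` covering every scored cell; the
#'   `label` column to group by is chosen with `label_col`.
#' @param label_col `"label_original"` (default) or `"label_medium"`.
#' @return Signatures x cell-types matrix of unweighted means.
#' @export
celltype_score_matrix <- function(scores, ann, label_col = "label_original") {
  cells <- colnames(scores)
  idx <- match(cells, ann$cell_id)
  if (anyNA(idx)) stop("unannotated scored cell(s): ",
                       paste(utils::head(cells[is.na(idx)], 5), collapse = ", "))
  labels <- ann[[label_col]][idx]
  if (anyNA(labels)) stop("NA labels in column ", label_col)
  types <- unique(labels)
  out <- vapply(types, function(t) rowMeans(scores[, labels == t, drop = FALSE]),
                numeric(nrow(scores)))
  out <- matrix(out, nrow = nrow(scores),
                dimnames = list(rownames(scores), types))
  out
}

#' Per-dataset cell-type score matrices for a signature set
#'
#' Z-scales each dataset's log-normalized matrix, scores all signatures per
#' cell, and averages scores within the dataset's annotated cell types.
#'
#' @param collection Lognorm-layer `DatasetCollection`.
#' @param sig A `SignatureSet`.
#' @param label_col Annotation column to group by.
#' @return Named list (by dataset) of signatures x cell-types matrices.
#' @export
per_dataset_celltype_scores <- function(collection, sig,
                                        label_col = "label_original") {
  stopifnot(inherits(collection, "DatasetCollection"))
  lapply(collection$datasets, function(d) {
    z <- zscale_genes(d$matrix)
    celltype_score_matrix(score_signature_set(z, sig), d$annotation, label_col)
  })
}

#' Annotate signatures by cross-dataset majority of score maxima
#'
#' A signature is assigned to the cell type that has the highest score in at
#' least `min_datasets` datasets. When no type reaches the threshold, or two
#' types tie for the maximal count of datasets, the signature stays
#' unassigned (`NA`).
#'
#' @param per_dataset Named list of signatures x cell-types score matrices.
#' @param min_datasets Minimum number of datasets (default 3).
#' @return Named character vector: signature id -> cell type or `NA`.
#' @export
annotate_signatures <- function(per_dataset, min_datasets = 3) {
  if (length(per_dataset) < min_datasets) {
    stop("need at least min_datasets (", min_datasets, ") score matrices")
  }
  ids <- rownames(per_dataset[[1]])
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    winners <- vapply(per_dataset, function(m) {
      v <- m[id, ]
      colnames(m)[which.max(v)]
    }, character(1))
    counts <- sort(table(winners), decreasing = TRUE)
    if (counts[1] >= min_datasets &&
        (length(counts) == 1 || counts[1] > counts[2])) {
      out[id] <- names(counts)[1]
    }
  }
  out
}

#' Wilcoxon enrichment of a signature in a cell type
#'
#' One-sided (greater) rank-sum test of the per-cell signature scores of the
#' target cell type against all other cells. The exact distribution is used
#' for small untied samples, the tie-corrected normal approximation
#' otherwise.
#'
#' @param scores Named per-cell score vector.
#' @param ann Cell annotation `data.frame` covering the scored cells.
#' @param celltype Target cell type (matched against `label_col`).
#' @param label_col Annotation column holding cell types.
#' @param dataset_id,signature_id Optional identifiers carried into the
#'   result.
#' @return List of class `EnrichmentResult`: `signature_id`, `celltype`,
#'   `dataset_id`, `p_value`, `direction` (`"higher"`/`"lower"`).
#' @export
enrichment_test <- function(scores, ann, celltype, label_col = "label_original",
                            dataset_id = NA_character_,
                            signature_id = NA_character_) {
  idx <- match(names(scores), ann$cell_id)
  if (anyNA(idx)) stop("unannotated scored cell(s)")
  labels <- ann[[label_col]][idx]
  x <- scores[labels == celltype]
  y <- scores[labels != celltype]
  if (!length(x) || !length(y)) {
    stop("need cells both inside and outside cell type ", celltype)
  }
  p <- stats::wilcox.test(x, y, alternative = "greater")$p.value
  structure(list(signature_id = signature_id, celltype = celltype,
                 dataset_id = dataset_id, p_value = p,
                 direction = if (stats::median(x) >= stats::median(y)) "higher" else "lower"),
            class = "EnrichmentResult")
}

#' Validate signature annotations by enrichment across datasets
#'
#' Tests every annotated signature for enrichment in its assigned cell type
#' in every dataset, and marks it validated when the one-sided rank-sum
#' p-value is below `alpha` in at least `min_datasets` datasets.
#'
#' @param collection Lognorm-layer `DatasetCollection`.
#' @param sig An annotated `SignatureSet`.
#' @param alpha Per-test significance threshold (default 0.01, uncorrected;
#'   set `adjust = "BH"` for Benjamini-Hochberg within each dataset).
#' @param min_datasets Required number of enriched datasets (default 3).
#' @param label_col Annotation column holding cell types.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per signature x dataset (p-values) plus a
#'   `validated` attribute: named logical per signature.
#' @export
validate_signatures <- function(collection, sig, alpha = 0.01, min_datasets = 3,
                                label_col = "label_original", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(sig, "SignatureSet"))
  if (is.null(sig$annotation)) stop("signature set carries no annotations to validate")
  rows <- list()
  for (ds in names(collection$datasets)) {
    d <- collection$datasets[[ds]]
    z <- zscale_genes(d$matrix)
    types <- unique(d$annotation[[label_col]])
    for (id in names(sig$annotation)) {
      ct <- sig$annotation[[id]]
      if (!ct %in% types) next
      sc <- suppressWarnings(mean_signature_score(z, sig$entries[[id]]))
      res <- enrichment_test(sc, d$annotation, ct, label_col, ds, id)
      rows[[length(rows) + 1]] <- data.frame(
        signature_id = id, celltype = ct, dataset_id = ds,
        p_value = res$p_value, direction = res$direction)
    }
  }
  tab <- do.call(rbind, rows)
  if (adjust == "BH" && !is.null(tab)) {
    tab$p_value <- stats::ave(tab$p_value, tab$dataset_id,
                              FUN = function(p) stats::p.adjust(p, "BH"))
  }
  validated <- vapply(names(sig$annotation), function(id) {
    sub <- tab[tab$signature_id == id, , drop = FALSE]
    sum(sub$p_value < alpha & sub$direction == "higher") >= min_datasets
  }, logical(1))
  attr(tab, "validated") <- validated
  tab
}

#' Per-gene Wilcoxon differential expression
#'
#' Two-sided rank-sum test per gene between two disjoint cell groups on
#' log-normalized expression; raw (uncorrected) p-values.
#'
#' @param m Lognorm-layer `ExpressionMatrix`.
#' @param groupA,groupB Disjoint non-empty cell id vectors.
#' @param genes Genes to test (absent genes skipped with a warning).
#' @return Named numeric vector of p-values.
#' @export
wilcoxon_dge <- function(m, groupA, groupB, genes = gene_ids(m)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("wilcoxon_dge expects a lognorm-layer matrix")
  if (!length(groupA) || !length(groupB)) stop("groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  absent <- setdiff(genes, gene_ids(m))
  if (length(absent)) {
    warning("skipping ", length(absent), " gene(s) absent from matrix")
    genes <- setdiff(genes, absent)
  }
  a <- m$values[genes, groupA, drop = FALSE]
  b <- m$values[genes, groupB, drop = FALSE]
  p <- vapply(seq_along(genes), function(i) {
    x <- a[i, ]; y <- b[i, ]
    if (stats::var(c(x, y)) == 0) return(1)  # constant gene: no evidence
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
  }, numeric(1))
  stats::setNames(p, genes)
}

#' Compare two per-gene p-value vectors
#'
#' Pairs p-values on the -log10 scale and summarizes the fraction of genes
#' where `pB` is smaller than `pA` (ties not counted) -- smaller `pB` across
#' the board indicates over-optimistic significance in the B analysis.
#'
#' @param pA,pB Named numeric vectors over the same gene universe (extra
#'   genes are dropped with a warning).
#' @return List with `table` (gene, p_a, p_b, neglog10_a, neglog10_b) and
#'   `fraction_below` (share with `pB < pA`).
#' @export
compare_pvalues <- function(pA, pB) {
  common <- intersect(names(pA), names(pB))
  if (!length(common)) stop("no shared genes between p-value vectors")
  if (length(common) < length(pA) || length(common) < length(pB)) {
    warning("gene sets differ; intersecting to ", length(common), " genes")
  }
  a <- pA[common]; b <- pB[common]
  list(table = data.frame(gene = common, p_a = unname(a), p_b = unname(b),
                          neglog10_a = -log10(unname(a)),
                          neglog10_b = -log10(unname(b))),
       fraction_below = sum(b < a) / length(common))
}

#' Jaccard index of two gene sets
#' @param a,b Non-empty character vectors (treated as sets).
#' @return `|a & b| / |a | b|` in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("sets must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Szymkiewicz-Simpson overlap coefficient of two gene sets
#' @param a,b Non-empty character vectors (treated as sets).
#' @return `|a & b| / min(|a|, |b|)` in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) stop("sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Long-format export of per-dataset cell-type scores
#'
#' @param per_dataset Named list of signatures x cell-types matrices.
#' @return data.frame with columns signature, celltype, dataset, score,
#'   ready for heatmap plotting or TSV export.
#' @export
scores_long <- function(per_dataset) {
  rows <- lapply(names(per_dataset), function(ds) {
    m <- per_dataset[[ds]]
    data.frame(signature = rep(rownames(m), times = ncol(m)),
               celltype = rep(colnames(m), each = nrow(m)),
               dataset = ds, score = as.vector(m))
  })
  do.call(rbind, rows)
}
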