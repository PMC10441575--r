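#' Quality-control filtering of cells and genes
#'
#' Removes cells expressing fewer than `min_genes_per_cell` genes and genes
#' expressed (count > 0) in fewer than `min_cells_per_gene` cells. Cells are
#' filtered first, then genes, so the gene filter is evaluated on the
#' retained cells only; the operation is idempotent.
#'
#' @param m Counts-layer `ExpressionMatrix`.
#' @param min_genes_per_cell Minimum number of detected genes per cell.
#' @param min_cells_per_gene Minimum number of cells a gene must be detected
#'   in.
#' @return Filtered counts-layer `ExpressionMatrix`.
#' @export
qc_filter <- function(m, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("qc_filter expects a counts-layer matrix")
  det <- m$values > 0
  keep_cells <- colSums(det) >= min_genes_per_cell
  if (!any(keep_cells)) stop("qc_filter removed all cells (min_genes_per_cell = ",
                             min_genes_per_cell, ")")
  det <- det[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(det) >= min_cells_per_gene
  expression_matrix(m$values[keep_genes, keep_cells, drop = FALSE], "counts")
}

#' Log-normalize counts per cell
#'
#' Per-cell normalization `ln(1 + scale_factor * count / cell_total)`, the
#' standard "LogNormalize" transform.
#'
#' @param m Counts-layer `ExpressionMatrix`; every cell total must be > 0.
#' @param scale_factor Library-size scale factor (default 10,000).
#' @return `ExpressionMatrix` with layer `"lognorm"`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("log_normalize expects a counts-layer matrix")
  totals <- colSums(m$values)
  if (any(totals == 0)) {
    stop("cells with zero total counts present; run qc_filter first")
  }
  v <- log1p(sweep(m$values, 2, totals / scale_factor, "/"))
  expression_matrix(v, "lognorm")
}

# Per-dataset standardized variance: gene variance divided by the median
# variance of genes with similar mean expression (equal-count mean bins),
# removing the mean-variance trend without a smoother.
.standardized_variance <- function(values, nbins = 20) {
  mu <- rowMeans(values)
  v <- apply(values, 1, stats::var)
  nbins <- max(1L, min(nbins, floor(nrow(values) / 2)))
  bins <- if (nbins == 1L) rep(1L, length(mu)) else {
    as.integer(cut(rank(mu, ties.method = "first"), breaks = nbins, labels = FALSE))
  }
  ref <- tapply(v, bins, stats::median)
  ref[ref <= 0] <- min(ref[ref > 0], 1)
  v / as.numeric(ref[as.character(bins)])
}

#' Select highly variable genes across datasets
#'
#' Within each dataset, genes are scored by a standardized variance of their
#' log-normalized expression (variance relative to the median variance of
#' genes of similar mean, computed in equal-count mean bins) and ranked.
#' Ranks are aggregated across datasets by their median, and the top `n`
#' genes present in every dataset are returned.
#'
#' @param collection `DatasetCollection` with all matrices in the lognorm
#'   layer.
#' @param n Number of genes to select (default 3000).
#' @param nbins Number of mean bins for the variance standardization.
#' @return Character vector of at most `n` gene ids.
#' @export
select_hvgs <- function(collection, n = 3000, nbins = 20) {
  stopifnot(inherits(collection, "DatasetCollection"))
  if (n <= 0) stop("`n` must be positive")
  for (id in names(collection$datasets)) {
    if (collection$datasets[[id]]$matrix$layer != "lognorm") {
      stop("dataset ", id, " is not in the lognorm layer")
    }
  }
  genes <- common_genes(collection)
  if (!length(genes)) stop("datasets share no genes")
  ranks <- vapply(collection$datasets, function(d) {
    sv <- .standardized_variance(d$matrix$values[genes, , drop = FALSE], nbins)
    rank(-sv, ties.method = "first")
  }, numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes))
  med <- apply(ranks, 1, stats::median)
  ord <- order(med, seq_along(genes))
  if (length(genes) < n) {
    warning("only ", length(genes), " common genes available (requested ", n, ")")
    n <- length(genes)
  }
  genes[ord[seq_len(n)]]
}

#' Z-scale each gene across cells
#'
#' Mean-centers and standardizes each gene row using the sample standard
#' deviation (n - 1). Constant genes map to all-zero rows.
#'
#' @param m Lognorm-layer `ExpressionMatrix`.
#' @return `ExpressionMatrix` with layer `"zscore"`.
#' @export
zscale_genes <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("zscale_genes expects a lognorm-layer matrix")
  mu <- rowMeans(m$values)
  sds <- apply(m$values, 1, stats::sd)
  v <- sweep(m$values, 1, mu, "-")
  nz <- sds > 0
  v[nz, ] <- v[nz, , drop = FALSE] / sds[nz]
  v[!nz, ] <- 0
  expression_matrix(v, "zscore")
}

#' Integrate a collection by per-dataset Z-scaling on shared HVGs
#'
#' The built-in integration fallback: restrict every dataset to a common set
#' of highly variable genes, Z-scale genes within each dataset (removing
#' per-dataset location/scale differences, i.e. additive batch effects on the
#' log scale), and concatenate cells. Anchor-based integration from external
#' tooling can be supplied instead wherever a zscore-layer matrix is
#' accepted.
#'
#' @param collection `DatasetCollection`, lognorm layer.
#' @param hvgs Genes to use (default: [select_hvgs()] with `n_hvgs`).
#' @param n_hvgs Number of HVGs when `hvgs` is not given.
#' @return List with `matrix` (zscore-layer `ExpressionMatrix`, cells from
#'   all datasets) and `annotation` (combined cell annotations).
#' @export
integrate_collection <- function(collection, hvgs = NULL, n_hvgs = 3000) {
  stopifnot(inherits(collection, "DatasetCollection"))
  if (is.null(hvgs)) {
    hvgs <- suppressWarnings(select_hvgs(collection, n = n_hvgs))
  } else {
    missing <- setdiff(hvgs, common_genes(collection))
    if (length(missing)) stop("hvgs absent from some dataset: ",
                              paste(utils::head(missing, 5), collapse = ", "))
  }
  mats <- list()
  anns <- list()
  for (id in names(collection$datasets)) {
    d <- collection$datasets[[id]]
    z <- zscale_genes(subset_matrix(d$matrix, genes = hvgs))
    v <- z$values
    colnames(v) <- paste(id, colnames(v), sep = ".")
    mats[[id]] <- v
    ann <- d$annotation
    ann$cell_id <- paste(id, ann$cell_id, sep = ".")
    anns[[id]] <- ann
  }
  combined <- expression_matrix(do.call(cbind, mats), "zscore")
  list(matrix = combined, annotation = do.call(rbind, c(anns, list(make.row.names = FALSE))))
}
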