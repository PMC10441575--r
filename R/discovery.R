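#' Embed genes into two dimensions with UMAP
#'
#' Runs UMAP on the gene dimension of a Z-scaled expression matrix (each
#' point is a gene; its feature vector is the gene's Z-scaled profile across
#' cells), keeping the first and second components. Single-threaded and
#' seeded, so coordinates are deterministic for fixed inputs.
#'
#' @param z Zscore-layer `ExpressionMatrix`.
#' @param seed Integer seed.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param pca Reduce gene profiles to this many principal components before
#'   building the UMAP graph (default 20; `NULL` disables). Denoises the
#'   profiles so that small co-expression modules stay compact in the layout.
#' @return An object of class `GeneEmbedding` with `gene_ids`, `coords`
#'   (genes x 2) and `seed`.
#' @export
embed_genes <- function(z, seed = 42L, n_neighbors = 15, min_dist = 0.1,
                        pca = 20) {
  stopifnot(inherits(z, "ExpressionMatrix"))
  if (z$layer != "zscore") stop("embed_genes expects a zscore-layer matrix")
  if (nrow(z$values) < 3) stop("need at least 3 genes to embed")
  if (!all(is.finite(z$values))) stop("non-finite values in input matrix")
  n_neighbors <- min(n_neighbors, nrow(z$values) - 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (!is.null(pca)) pca <- min(pca, nrow(z$values) - 1, ncol(z$values) - 1)
  coords <- uwot::umap(z$values, n_components = 2, n_neighbors = n_neighbors,
                       min_dist = min_dist, pca = pca,
                       n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
  dimnames(coords) <- list(gene_ids(z), c("UMAP1", "UMAP2"))
  structure(list(gene_ids = gene_ids(z), coords = coords, seed = as.integer(seed)),
            class = "GeneEmbedding")
}

#' Knee point of an ascending curve
#'
#' Kneedle-style detector: normalizes the sorted values against their index,
#' and returns the position of maximum perpendicular distance to the chord
#' joining the curve endpoints. If the curve is (numerically) a straight
#' line, the midpoint is returned with a warning.
#'
#' @param values Numeric vector, sorted ascending (sorted internally if not).
#' @return List with `index` and `value` of the knee.
#' @export
knee_point <- function(values) {
  y <- sort(values)
  n <- length(y)
  if (n < 3) stop("need at least 3 values")
  x <- seq_len(n)
  # perpendicular distance of each point to the chord (x1,y1)-(xn,yn)
  dx <- n - 1
  dy <- y[n] - y[1]
  norm <- sqrt(dx^2 + dy^2)
  perp <- abs(dy * (x - 1) - dx * (y - y[1])) / norm
  if (max(perp) < 1e-12 * max(1, abs(y[n]))) {
    warning("curve has no detectable knee (collinear); returning midpoint")
    idx <- ceiling(n / 2)
    return(list(index = idx, value = y[idx]))
  }
  idx <- which.max(perp)
  list(index = idx, value = y[idx])
}

#' Epsilon selection from the k-nearest-neighbor distance curve
#'
#' Computes each gene's distance to its k-th nearest neighbor in the
#' embedding, sorts the distances ascending, and returns the value at the
#' knee (point of maximum curvature) as a DBSCAN epsilon candidate. The
#' default `k` mirrors the minPts used for clustering.
#'
#' @param e A `GeneEmbedding`.
#' @param k Neighbor order (default 10).
#' @return The knee distance (numeric scalar).
#' @export
knee_epsilon <- function(e, k = 10) {
  stopifnot(inherits(e, "GeneEmbedding"))
  n <- nrow(e$coords)
  if (k >= n) stop("`k` must be smaller than the number of genes (", n, ")")
  knee_point(knn_distances(e, k))$value
}

# k-th nearest-neighbor distance per gene in the embedding
knn_distances <- function(e, k) {
  d <- as.matrix(stats::dist(e$coords))
  apply(d, 1, function(row) sort(row[-which.min(row)], partial = k)[k])
}

#' Dense-quantile epsilon for small, tight gene modules
#'
#' The knee of the full k-NN distance curve tracks the break between the
#' bulk of genes and outliers, which is often far above the scale of small
#' dense gene modules; higher-resolution clustering needs an epsilon below
#' the knee. This helper returns a low quantile of the k-NN distances, so
#' that roughly `dense_fraction` of genes qualify as core points -- the
#' analogue of manually picking an epsilon below the knee to resolve more
#' clusters.
#'
#' @param e A `GeneEmbedding`.
#' @param k Neighbor order (pair with the DBSCAN minPts).
#' @param dense_fraction Target fraction of genes in dense regions
#'   (default 0.1).
#' @return Numeric epsilon.
#' @export
dense_epsilon <- function(e, k = 10, dense_fraction = 0.1) {
  stopifnot(inherits(e, "GeneEmbedding"))
  n <- nrow(e$coords)
  if (k >= n) stop("`k` must be smaller than the number of genes (", n, ")")
  if (dense_fraction <= 0 || dense_fraction > 1) {
    stop("`dense_fraction` must be in (0, 1]")
  }
  as.numeric(stats::quantile(knn_distances(e, k), dense_fraction))
}

#' Density-based clustering of the gene embedding (DBSCAN)
#'
#' Canonical DBSCAN with Euclidean metric on the 2-D embedding. The
#' epsilon-neighborhood is closed (distance <= epsilon) and includes the
#' point itself; a point with at least `min_pts` neighbors is a core point.
#' Genes in no dense region get the noise label 0. Cluster ids are contiguous
#' from 1, ordered by the first core point encountered in input gene order;
#' border points are claimed by the first cluster that reaches them in that
#' deterministic scan order.
#'
#' @param e A `GeneEmbedding`.
#' @param epsilon Neighborhood radius (default 0.18, the reference workflow's
#'   tuned value on UMAP coordinates).
#' @param min_pts Minimum points forming a dense neighborhood (default 10).
#' @return An object of class `GeneClustering` with `gene_ids`, integer
#'   `labels` (0 = noise), `epsilon`, `min_pts`.
#' @export
cluster_genes <- function(e, epsilon = 0.18, min_pts = 10) {
  stopifnot(inherits(e, "GeneEmbedding"))
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (min_pts < 1) stop("`min_pts` must be >= 1")
  labels <- dbscan_labels(e$coords, epsilon, min_pts)
  structure(list(gene_ids = e$gene_ids, labels = labels,
                 epsilon = epsilon, min_pts = as.integer(min_pts)),
            class = "GeneClustering")
}

# DBSCAN on a coordinate matrix; returns integer labels (0 = noise).
dbscan_labels <- function(coords, epsilon, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= epsilon))
  is_core <- vapply(neighbors, length, integer(1)) >= min_pts
  labels <- integer(n)      # 0 = unvisited/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !is_core[i]) next
    cl <- cl + 1L
    # expand cluster from seed core point i (BFS over core points)
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in neighbors[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (!visited[q] && is_core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  names(labels) <- rownames(coords)
  labels
}

#' Per-gene silhouette scores on correlation distance
#'
#' Silhouette widths for the non-noise genes of a clustering, computed on the
#' gene-by-gene correlation distance matrix `d(x, y) = 1 - r(x, y)` where `r`
#' is the Pearson correlation of the genes' Z-scaled profiles. Noise genes
#' are excluded; singleton clusters get silhouette 0.
#'
#' @param z Zscore-layer `ExpressionMatrix` containing all clustered genes.
#' @param clustering A `GeneClustering` over genes of `z`.
#' @return An object of class `SilhouetteReport` with `per_gene` (named
#'   numeric in `[-1, 1]`) and `per_cluster` (mean over member genes).
#' @export
gene_silhouettes <- function(z, clustering) {
  stopifnot(inherits(z, "ExpressionMatrix"), inherits(clustering, "GeneClustering"))
  if (z$layer != "zscore") stop("gene_silhouettes expects a zscore-layer matrix")
  keep <- clustering$labels > 0
  labels <- clustering$labels[keep]
  genes <- clustering$gene_ids[keep]
  if (length(unique(labels)) < 2) {
    stop("silhouette undefined for fewer than 2 clusters")
  }
  missing <- setdiff(genes, gene_ids(z))
  if (length(missing)) stop("clustered genes absent from matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  d <- correlation_distance(z$values[genes, , drop = FALSE])
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  per_gene <- stats::setNames(sil[, "sil_width"], genes)
  per_cluster <- tapply(per_gene, labels, mean)
  structure(list(per_gene = per_gene,
                 per_cluster = stats::setNames(as.numeric(per_cluster),
                                               names(per_cluster))),
            class = "SilhouetteReport")
}

#' Correlation distance between gene profiles
#' @param values Genes x cells numeric matrix.
#' @return Symmetric matrix of `1 - Pearson r` between rows.
#' @export
correlation_distance <- function(values) {
  1 - stats::cor(t(values))
}

#' Refine gene clusters into candidate signatures
#'
#' Applies the first three refinement filters in order: (I) drop genes with
#' negative silhouette; (II) drop clusters left with fewer than `min_size`
#' genes; (III) keep the `top_k` genes per cluster by descending silhouette
#' (ties broken by input gene order). Genes within each resulting signature
#' are ordered by descending silhouette. The fourth filter, on cell-type
#' score contrasts, is [max_median_filter()].
#'
#' @param clustering A `GeneClustering`.
#' @param silhouettes Matching `SilhouetteReport`.
#' @param min_size Minimum cluster size after filter I (default 10).
#' @param top_k Genes kept per cluster (default 50).
#' @return A `SignatureSet` with ids `S_<cluster>`; possibly empty.
#' @export
refine_gene_clusters <- function(clustering, silhouettes, min_size = 10, top_k = 50) {
  stopifnot(inherits(clustering, "GeneClustering"),
            inherits(silhouettes, "SilhouetteReport"))
  keep <- clustering$labels > 0
  genes <- clustering$gene_ids[keep]
  labels <- clustering$labels[keep]
  if (!all(genes %in% names(silhouettes$per_gene))) {
    stop("silhouettes were not computed on this clustering")
  }
  s <- silhouettes$per_gene[genes]
  # I: negative-silhouette genes out
  ok <- s >= 0
  genes <- genes[ok]; labels <- labels[ok]; s <- s[ok]
  entries <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    # II: minimum cluster size
    if (length(idx) < min_size) next
    # III: top_k by descending silhouette, ties by input order
    ord <- idx[order(-s[idx], idx)]
    ord <- ord[seq_len(min(top_k, length(ord)))]
    entries[[paste0("S_", cl)]] <- unname(genes[ord])
  }
  signature_set(entries)
}

#' Max-median filter flagging program-like gene clusters
#'
#' A signature that is not cell-type specific (e.g. an interferon-response or
#' cell-cycle program) shows a small contrast between the cell type with the
#' maximum score and the cell type with the median score. A signature is
#' removed when that contrast is below `delta` (strict) in at least
#' `min_datasets` datasets.
#'
#' @param sig A `SignatureSet`.
#' @param per_dataset_celltype_scores Named list (one element per dataset) of
#'   signature x cell-type score matrices from [celltype_score_matrix()].
#' @param delta Contrast threshold in average Z-score units (default 0.6).
#' @param min_datasets Number of low-contrast datasets triggering removal
#'   (default 3).
#' @return The filtered `SignatureSet` (retained signatures unchanged).
#' @export
max_median_filter <- function(sig, per_dataset_celltype_scores, delta = 0.6,
                              min_datasets = 3) {
  stopifnot(inherits(sig, "SignatureSet"))
  ids <- names(sig$entries)
  low_counts <- stats::setNames(integer(length(ids)), ids)
  for (ds in names(per_dataset_celltype_scores)) {
    m <- per_dataset_celltype_scores[[ds]]
    missing <- setdiff(ids, rownames(m))
    if (length(missing)) {
      stop("signature(s) missing from score matrix of ", ds, ": ",
           paste(missing, collapse = ", "))
    }
    contrast <- apply(m[ids, , drop = FALSE], 1, function(v) max(v) - stats::median(v))
    low_counts <- low_counts + (contrast < delta)
  }
  keep <- ids[low_counts < min_datasets]
  signature_set(sig$entries[keep],
                if (!is.null(sig$annotation)) sig$annotation[intersect(names(sig$annotation), keep)])
}

#' Run the full signature discovery workflow
#'
#' Chains QC, log-normalization, HVG selection, per-dataset Z-scaling
#' integration, gene-space UMAP, DBSCAN (epsilon from the k-NN knee unless
#' given), silhouette computation, the three silhouette-based refinement
#' filters, per-dataset cell-type scoring, the max-median program filter, and
#' cross-dataset majority annotation.
#'
#' @param collection Counts-layer `DatasetCollection`.
#' @param n_hvgs Number of highly variable genes for integration.
#' @param seed Seed for the embedding.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param epsilon DBSCAN radius; `NULL` (default) selects a dense-quantile
#'   epsilon from the k-NN distance curve with `k = min_pts` (see
#'   [dense_epsilon()]); [knee_epsilon()] gives the coarser knee candidate.
#' @param dense_fraction Passed to [dense_epsilon()] when `epsilon` is
#'   `NULL`.
#' @param min_pts DBSCAN minPts and the minimum refined cluster size.
#' @param top_k Genes kept per signature.
#' @param delta,min_datasets Max-median filter parameters.
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds.
#' @return List with the refined annotated `signatures`, plus intermediates
#'   (`embedding`, `clustering`, `silhouettes`, `scores` per dataset,
#'   `epsilon`, and a `funnel` data.frame of cluster/gene counts after each
#'   step).
#' @export
discover_signatures <- function(collection, n_hvgs = 3000, seed = 42L,
                                n_neighbors = 15, min_dist = 0.1,
                                epsilon = NULL, min_pts = 10, top_k = 50,
                                delta = 0.6, min_datasets = 3,
                                min_genes_per_cell = 200, min_cells_per_gene = 3,
                                dense_fraction = 0.1) {
  stopifnot(inherits(collection, "DatasetCollection"))
  norm <- list()
  for (id in names(collection$datasets)) {
    d <- collection$datasets[[id]]
    filt <- qc_filter(d$matrix, min_genes_per_cell, min_cells_per_gene)
    ann <- d$annotation[d$annotation$cell_id %in% cell_ids(filt), , drop = FALSE]
    norm[[id]] <- list(matrix = log_normalize(filt), annotation = ann)
  }
  norm <- dataset_collection(norm)
  hvgs <- suppressWarnings(select_hvgs(norm, n = n_hvgs))
  integrated <- integrate_collection(norm, hvgs = hvgs)

  embedding <- embed_genes(integrated$matrix, seed = seed,
                           n_neighbors = n_neighbors, min_dist = min_dist)
  if (is.null(epsilon)) {
    epsilon <- dense_epsilon(embedding, k = min_pts, dense_fraction = dense_fraction)
  }
  clustering <- cluster_genes(embedding, epsilon = epsilon, min_pts = min_pts)
  silhouettes <- gene_silhouettes(integrated$matrix, clustering)
  refined <- refine_gene_clusters(clustering, silhouettes,
                                  min_size = min_pts, top_k = top_k)

  funnel <- data.frame(
    step = c("clusters", "refined"),
    n_clusters = c(length(unique(clustering$labels[clustering$labels > 0])),
                   length(refined)),
    n_genes = c(sum(clustering$labels > 0),
                length(signature_genes(refined)))
  )

  scores <- per_dataset_celltype_scores(norm, refined)
  final <- max_median_filter(refined, scores, delta = delta,
                             min_datasets = min_datasets)
  funnel <- rbind(funnel, data.frame(step = "max_median", n_clusters = length(final),
                                     n_genes = length(signature_genes(final))))
  ann <- annotate_signatures(lapply(scores, function(m) {
    m[names(final$entries), , drop = FALSE]
  }), min_datasets = min_datasets)
  assigned <- ann[!is.na(ann)]
  final <- signature_set(final$entries,
                         if (length(assigned)) assigned else NULL)
  list(signatures = final, embedding = embedding, clustering = clustering,
       silhouettes = silhouettes, scores = scores, epsilon = epsilon,
       funnel = funnel)
}

#' Scan DBSCAN epsilon candidates
#'
#' Runs clustering and silhouette refinement for each epsilon in `grid` and
#' returns the refined sets plus per-dataset cell-type score matrices, for
#' manual inspection (e.g. heatmaps); no automatic choice is made.
#'
#' @param embedding A `GeneEmbedding`.
#' @param z Zscore-layer matrix the embedding came from.
#' @param collection Lognorm `DatasetCollection` for scoring.
#' @param grid Numeric vector of epsilon values.
#' @param min_pts,top_k Refinement parameters.
#' @return Named list (by epsilon) of lists with `signatures` and `scores`.
#' @export
epsilon_scan <- function(embedding, z, collection, grid = c(0.15, 0.2),
                         min_pts = 10, top_k = 50) {
  out <- list()
  for (eps in grid) {
    clustering <- cluster_genes(embedding, epsilon = eps, min_pts = min_pts)
    res <- if (length(unique(clustering$labels[clustering$labels > 0])) < 2) {
      list(signatures = signature_set(list()), scores = NULL)
    } else {
      sil <- gene_silhouettes(z, clustering)
      sig <- refine_gene_clusters(clustering, sil, min_size = min_pts, top_k = top_k)
      list(signatures = sig,
           scores = if (length(sig)) per_dataset_celltype_scores(collection, sig))
    }
    out[[as.character(eps)]] <- res
  }
  out
}
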