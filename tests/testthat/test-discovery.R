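test_that("identical seeds give identical embeddings and duplicates stay adjacent", {
  z <- toy_module_zscore(n_blocks = 2, block_size = 6, n_noise = 30, n_cells = 80)
  # plant an exact duplicate profile pair
  v <- z$values
  v["g002", ] <- v["g001", ]
  z <- expression_matrix(v, "zscore")
  e1 <- embed_genes(z, seed = 3L)
  e2 <- embed_genes(z, seed = 3L)
  expect_identical(e1$coords, e2$coords)
  d <- as.matrix(dist(e1$coords))
  dup_dist <- d["g001", "g002"]
  all_pairs <- d[upper.tri(d)]
  expect_lte(dup_dist, quantile(all_pairs, 0.1))
})

test_that("module structure is preserved in the embedding", {
  z <- toy_module_zscore(n_blocks = 3, block_size = 10, n_noise = 30)
  e <- embed_genes(z, seed = 11L)
  idx <- list(1:10, 11:20, 21:30)
  d <- as.matrix(dist(e$coords))
  within <- mean(unlist(lapply(idx, function(i) d[i, i][upper.tri(d[i, i])])))
  between <- mean(c(d[idx[[1]], idx[[2]]], d[idx[[1]], idx[[3]]], d[idx[[2]], idx[[3]]]))
  expect_lt(within, between)
  # non-finite input is rejected
  v <- z$values; v[1, 1] <- NA
  expect_error(embed_genes(expression_matrix(v, "zscore"), seed = 1L), "non-finite")
})

test_that("knee detection finds the breakpoint of a piecewise curve", {
  curve <- c(rep(0.1, 90), seq(0.1, 2.0, length.out = 11)[-1])
  k <- knee_point(curve)
  expect_gte(k$value, 0.1)
  expect_lte(k$value, 0.3)
  expect_warning(k2 <- knee_point(seq(0, 1, length.out = 50)), "collinear")
  expect_equal(k2$value, seq(0, 1, length.out = 50)[25])
  expect_warning(k3 <- knee_point(rep(0.4, 30)), "collinear")
  expect_equal(k3$value, 0.4)
})

test_that("knee_epsilon operates on embedding k-NN distances", {
  coords <- rbind(matrix(rnorm(180, sd = 0.05), ncol = 2),
                  matrix(rnorm(20, sd = 3), ncol = 2))
  rownames(coords) <- sprintf("g%03d", 1:100)
  e <- structure(list(gene_ids = rownames(coords), coords = coords, seed = 1L),
                 class = "GeneEmbedding")
  eps <- knee_epsilon(e, k = 5)
  expect_true(is.finite(eps) && eps > 0)
  expect_error(knee_epsilon(e, k = 100), "smaller")
  expect_lt(dense_epsilon(e, k = 5, dense_fraction = 0.1), eps)
})

test_that("DBSCAN clusters the hand-checked example", {
  coords <- rbind(c(0, 0), c(0, 0.1), c(0, 0.2), c(5, 5))
  rownames(coords) <- paste0("g", 1:4)
  e <- structure(list(gene_ids = rownames(coords), coords = coords, seed = 1L),
                 class = "GeneEmbedding")
  cl <- cluster_genes(e, epsilon = 0.15, min_pts = 2)
  expect_equal(unname(cl$labels), c(1L, 1L, 1L, 0L))
  # epsilon covering everything -> one cluster
  cl2 <- cluster_genes(e, epsilon = 100, min_pts = 2)
  expect_equal(unname(cl2$labels), rep(1L, 4))
  # min_pts = 1 leaves no noise
  cl3 <- cluster_genes(e, epsilon = 0.15, min_pts = 1)
  expect_true(all(cl3$labels > 0))
  expect_error(cluster_genes(e, epsilon = -1), "positive")
})

test_that("DBSCAN matches the brute-force oracle on random instances", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    coords <- matrix(rnorm(2 * n, sd = sample(c(0.3, 1), 1)), ncol = 2)
    rownames(coords) <- sprintf("g%04d", seq_len(n))
    eps <- runif(1, 0.1, 0.8)
    mp <- sample(2:8, 1)
    e <- structure(list(gene_ids = rownames(coords), coords = coords, seed = 1L),
                   class = "GeneEmbedding")
    got <- cluster_genes(e, eps, mp)$labels
    want <- oracle_dbscan(coords, eps, mp)
    expect_true(same_partition(unname(got), want),
                info = sprintf("instance %d (n=%d eps=%.2f minPts=%d)", i, n, eps, mp))
  }
})

make_clustering <- function(genes, labels, eps = 0.2, mp = 2) {
  structure(list(gene_ids = genes, labels = as.integer(labels),
                 epsilon = eps, min_pts = as.integer(mp)),
            class = "GeneClustering")
}

test_that("silhouettes match hand-evaluated and constructed cases", {
  # two clusters of duplicated profiles, orthogonal between clusters
  set.seed(2)
  f1 <- rnorm(50); f2 <- rnorm(50)
  f2 <- residuals(lm(f2 ~ f1))          # exactly uncorrelated with f1
  v <- rbind(f1, f1, f2, f2)
  dimnames(v) <- list(paste0("g", 1:4), paste0("c", 1:50))
  v <- t(scale(t(v)))
  z <- expression_matrix(v, "zscore")
  cl <- make_clustering(paste0("g", 1:4), c(1, 1, 2, 2))
  s <- gene_silhouettes(z, cl)
  expect_equal(unname(s$per_gene), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(s$per_cluster), c(1, 1), tolerance = 1e-10)

  # negative silhouette: gene anti-correlated with own cluster, duplicated in other
  v2 <- rbind(f1, f1, -f1, f2, f2, -f1)
  dimnames(v2) <- list(paste0("g", 1:6), paste0("c", 1:50))
  z2 <- expression_matrix(t(scale(t(v2))), "zscore")
  cl2 <- make_clustering(paste0("g", 1:6), c(1, 1, 1, 2, 2, 2))
  s2 <- gene_silhouettes(z2, cl2)
  expect_lt(s2$per_gene[["g3"]], 0)   # belongs with g6 in cluster 2

  # single cluster is undefined
  expect_error(gene_silhouettes(z, make_clustering(paste0("g", 1:4), c(1, 1, 1, 1))),
               "fewer than 2")
})

test_that("silhouettes agree with direct formula evaluation", {
  set.seed(4)
  for (i in 1:10) {
    z <- toy_module_zscore(n_blocks = 3, block_size = sample(4:8, 1),
                           n_noise = sample(5:20, 1), n_cells = 60,
                           seed = 100 + i)
    n <- nrow(z$values)
    labels <- sample(0:3, n, replace = TRUE)
    if (length(unique(labels[labels > 0])) < 2) next
    cl <- make_clustering(gene_ids(z), labels)
    got <- gene_silhouettes(z, cl)$per_gene
    keep <- labels > 0
    d <- correlation_distance(z$values[keep, , drop = FALSE])
    want <- oracle_silhouette(d, labels[keep])
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

make_sil <- function(genes, values) {
  structure(list(per_gene = stats::setNames(values, genes),
                 per_cluster = NULL), class = "SilhouetteReport")
}

test_that("refinement filters apply in order I -> II -> III", {
  # 12-gene cluster with 3 negatives drops below min_size and is removed
  genes <- sprintf("g%02d", 1:24)
  labels <- rep(c(1, 2), each = 12)
  sil <- make_sil(genes, c(c(rep(0.5, 9), -0.1, -0.2, -0.3), seq(0.9, 0.2, length.out = 12)))
  cl <- make_clustering(genes, labels)
  out <- refine_gene_clusters(cl, sil, min_size = 10, top_k = 50)
  expect_equal(names(out$entries), "S_2")
  expect_length(out$entries$S_2, 12)
  # gene order within a signature is by descending silhouette
  expect_equal(out$entries$S_2, genes[13:24])

  # 60 all-positive genes are capped at top 50
  genes2 <- sprintf("h%02d", 1:70)
  labels2 <- c(rep(1, 60), rep(2, 10))
  sil2 <- make_sil(genes2, c(seq(0.99, 0.4, length.out = 60), rep(0.5, 10)))
  out2 <- refine_gene_clusters(make_clustering(genes2, labels2), sil2)
  expect_length(out2$entries$S_1, 50)
  expect_equal(out2$entries$S_1, genes2[1:50])

  # already-refined input passes through unchanged (and re-refinement is a no-op)
  out3 <- refine_gene_clusters(make_clustering(genes2, labels2), sil2,
                               min_size = 10, top_k = 100)
  expect_equal(sapply(out3$entries, length), c(S_1 = 60L, S_2 = 10L))
  relabel <- rep(seq_along(out2$entries), times = lengths(out2$entries))
  regene <- unlist(out2$entries, use.names = FALSE)
  out4 <- refine_gene_clusters(make_clustering(regene, relabel),
                               make_sil(regene, sil2$per_gene[regene]))
  expect_equal(out4$entries, out2$entries)
})

test_that("max-median filter removes low-contrast signatures by the strict rule", {
  mk <- function(max, med) {
    # 5 cell types; engineer max and median
    m <- matrix(c(max, med, med, med - 0.1, med - 0.2), nrow = 1)
    dimnames(m) <- list("S_1", paste0("t", 1:5))
    m
  }
  sig <- signature_set(list(S_1 = c("A", "B")))
  # contrast 0.5 in 3 of 7 datasets -> removed
  scores <- c(lapply(1:3, function(i) mk(1.0, 0.5)),
              lapply(1:4, function(i) mk(2.0, 0.5)))
  names(scores) <- paste0("d", 1:7)
  expect_length(max_median_filter(sig, scores, delta = 0.6, min_datasets = 3), 0)
  # contrast 0.7 everywhere -> kept
  scores2 <- setNames(lapply(1:7, function(i) mk(1.2, 0.5)), paste0("d", 1:7))
  expect_equal(names(max_median_filter(sig, scores2)$entries), "S_1")
  # boundary: contrast exactly 0.6 everywhere -> kept (strict <)
  scores3 <- setNames(lapply(1:7, function(i) mk(1.1, 0.5)), paste0("d", 1:7))
  expect_equal(names(max_median_filter(sig, scores3)$entries), "S_1")
  # missing signature -> error
  bad <- scores2
  rownames(bad$d1) <- "S_9"
  expect_error(max_median_filter(sig, bad), "missing from score matrix")
})
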