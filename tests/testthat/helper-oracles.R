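# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's code paths.

# Textbook DBSCAN: O(n^2) neighborhood scan with recursive region growing,
# written against the original algorithm description.
oracle_dbscan <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  region <- function(i) which(d[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- region(i)
    if (length(nb) < min_pts) next   # noise unless claimed later
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(nb, i)
    while (length(seeds)) {
      j <- seeds[1]
      seeds <- seeds[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nbj <- region(j)
        if (length(nbj) >= min_pts) seeds <- union(seeds, nbj)
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

# Are two label vectors identical up to renaming of the non-noise labels?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  key <- tapply(b, a, function(v) length(unique(v)) == 1)
  key2 <- tapply(a, b, function(v) length(unique(v)) == 1)
  all(key) && all(key2)
}

# Silhouette widths evaluated directly from the definition on a full
# distance matrix (labels > 0 only; singletons -> 0).
oracle_silhouette <- function(d, labels) {
  n <- length(labels)
  out <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { out[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    out[i] <- (b - a) / max(a, b)
  }
  out
}

# One-vs-rest metrics computed from scratch with explicit counting loops.
oracle_metrics <- function(pred, truth, classes) {
  res <- list()
  n <- length(truth)
  for (cl in classes) {
    tp <- 0; fp <- 0; tn <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      else if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      else if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
      else tn <- tn + 1
    }
    div <- function(x, y) if (y == 0) 0 else x / y
    sens <- div(tp, tp + fn); ppv <- div(tp, tp + fp)
    res[[cl]] <- c(accuracy = (tp + tn) / n,
                   sensitivity = sens,
                   specificity = div(tn, tn + fp),
                   NPV = div(tn, tn + fn),
                   PPV = ppv,
                   F1 = div(2 * ppv * sens, ppv + sens))
  }
  res
}

# Small deterministic counts matrix with named dims.
toy_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  expression_matrix(m, "counts")
}

# Zscore-layer matrix with planted correlated gene blocks: each block shares
# a latent factor; remaining genes are independent noise.
toy_module_zscore <- function(n_blocks = 3, block_size = 8, n_noise = 20,
                              n_cells = 120, strength = 1.5, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_blocks)) {
    f <- rnorm(n_cells)
    for (g in seq_len(block_size)) {
      rows[[length(rows) + 1]] <- strength * f + rnorm(n_cells)
    }
  }
  for (g in seq_len(n_noise)) rows[[length(rows) + 1]] <- rnorm(n_cells)
  v <- do.call(rbind, rows)
  dimnames(v) <- list(sprintf("g%03d", seq_len(nrow(v))),
                      sprintf("c%03d", seq_len(n_cells)))
  v <- t(scale(t(v)))
  expression_matrix(v, "zscore")
}
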