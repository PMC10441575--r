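#' Default medium-level PBMC label map
#'
#' Maps common author-level PBMC cell-type labels to medium-depth classes
#' (B, DC, pDC, Monocytes, NK, CD4 T, CD8 T, Plasma). The table is a
#' reconstruction covering widespread label vocabularies and is fully
#' overridable: supply your own two-column table to [harmonize_labels()].
#'
#' @return data.frame with columns `original` and `medium`.
#' @export
default_label_map <- function() {
  utils::read.delim(system.file("extdata", "pbmc_medium_label_map.tsv",
                                package = "immunosig", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Harmonize cell-type labels to a medium depth level
#'
#' Fills the `label_medium` column of an annotation table from a mapping of
#' original to medium-level labels. Unmapped labels are handled per policy:
#' dropped (default), kept as-is, or raised as an error.
#'
#' @param ann Cell annotation `data.frame`.
#' @param map data.frame with columns `original`, `medium` (default: the
#'   shipped PBMC map). Must be a function: no original label may map to two
#'   targets.
#' @param unmapped `"drop"`, `"keep"` or `"error"`.
#' @return Annotation `data.frame` with `label_medium` set.
#' @export
harmonize_labels <- function(ann, map = default_label_map(),
                             unmapped = c("drop", "keep", "error")) {
  unmapped <- match.arg(unmapped)
  if (!all(c("original", "medium") %in% names(map))) {
    stop("`map` must have columns `original` and `medium`")
  }
  if (anyDuplicated(map$original)) {
    stop("label map is not a function; duplicated original label(s): ",
         paste(unique(map$original[duplicated(map$original)]), collapse = ", "))
  }
  idx <- match(ann$label_original, map$original)
  miss <- is.na(idx)
  if (any(miss) && unmapped == "error") {
    stop("unmapped label(s): ", paste(unique(ann$label_original[miss]), collapse = ", "))
  }
  ann$label_medium <- map$medium[idx]
  if (unmapped == "keep") ann$label_medium[miss] <- ann$label_original[miss]
  if (unmapped == "drop") ann <- ann[!miss, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Random 67:33 train/test split of cells
#'
#' Simple random sampling (not stratified) into disjoint, exhaustive train
#' and test sets; reproducible for a fixed seed. `round(train_fraction * n)`
#' cells go to training.
#'
#' @param cells Character vector of cell ids (>= 2).
#' @param train_fraction Fraction in (0, 1), default 0.67.
#' @param seed Integer seed.
#' @param stratify_by Optional factor aligned with `cells`; when given, the
#'   split is drawn within each level (useful for tiny classes).
#' @return List with `train` and `test` cell id vectors.
#' @export
split_train_test <- function(cells, train_fraction = 0.67, seed = 1L,
                             stratify_by = NULL) {
  if (length(cells) < 2) stop("need at least 2 cells to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (is.null(stratify_by)) {
    n_train <- round(train_fraction * length(cells))
    train <- sample(cells, n_train)
  } else {
    stopifnot(length(stratify_by) == length(cells))
    train <- unlist(lapply(split(cells, stratify_by), function(cc) {
      sample(cc, round(train_fraction * length(cc)))
    }), use.names = FALSE)
  }
  train <- cells[sort(match(train, cells))]  # keep input order
  list(train = train, test = setdiff(cells, train))
}

#' Train a random forest cell-type classifier on signature genes
#'
#' Features are the intersection of the signature genes, the reference
#' genes, and the query dataset's genes (so train and query feature spaces
#' match). Feature values are the Z-scaled expression of those genes in the
#' training cells; training-set per-gene means and standard deviations are
#' stored for optional reuse at prediction time.
#'
#' @param ref Lognorm-layer `ExpressionMatrix` (training cells).
#' @param ann Harmonized annotation covering the training cells
#'   (`label_medium` set).
#' @param sig A `SignatureSet` providing the feature genes.
#' @param query_genes Genes available in the query dataset (default: all
#'   reference genes).
#' @param n_trees Number of trees (default 500); features per split default
#'   to `floor(sqrt(p))`.
#' @param seed Integer seed for the forest.
#' @return An object of class `TrainedClassifier`.
#' @export
train_classifier <- function(ref, ann, sig, query_genes = gene_ids(ref),
                             n_trees = 500, seed = 1L) {
  stopifnot(inherits(ref, "ExpressionMatrix"), inherits(sig, "SignatureSet"))
  if (ref$layer != "lognorm") stop("train_classifier expects a lognorm reference")
  features <- intersect(intersect(signature_genes(sig), gene_ids(ref)), query_genes)
  if (!length(features)) stop("no common signature genes between reference and query")
  idx <- match(cell_ids(ref), ann$cell_id)
  if (anyNA(idx)) stop("unannotated reference cell(s)")
  labels <- ann$label_medium[idx]
  if (anyNA(labels)) stop("reference annotations are not harmonized (label_medium missing)")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")

  z <- zscale_genes(subset_matrix(ref, genes = features))
  x <- t(z$values)
  y <- factor(labels, levels = classes)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  forest <- randomForest::randomForest(x = x, y = y, ntree = n_trees)
  scaling <- data.frame(
    gene = features,
    mean = rowMeans(subset_matrix(ref, genes = features)$values),
    sd = apply(subset_matrix(ref, genes = features)$values, 1, stats::sd))
  structure(list(model = forest, feature_genes = features, classes = classes,
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 scaling_stats = scaling),
            class = "TrainedClassifier")
}

#' @export
print.TrainedClassifier <- function(x, ...) {
  cat(sprintf("TrainedClassifier: %d trees, %d feature genes, %d classes (%s)\n",
              x$n_trees, length(x$feature_genes), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Predict cell types for a query dataset
#'
#' Z-scales the query's feature genes -- by default with the query's own
#' per-gene statistics, mirroring per-dataset Z-scaled matrices; set
#' `scaling = "train"` to reuse the training statistics instead -- and
#' assigns each cell the majority vote over trees.
#'
#' @param model A `TrainedClassifier`.
#' @param query Lognorm-layer `ExpressionMatrix` containing every feature
#'   gene.
#' @param scaling `"query"` (default) or `"train"`.
#' @param min_vote_share Optional cutoff in (0, 1]; cells whose winning class
#'   receives a lower share of tree votes are labeled `NA` (off by default —
#'   every cell is assigned).
#' @return Named character vector of predicted labels.
#' @export
predict_cells <- function(model, query, scaling = c("query", "train"),
                          min_vote_share = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(model, "TrainedClassifier"), inherits(query, "ExpressionMatrix"))
  if (query$layer != "lognorm") stop("predict_cells expects a lognorm query")
  missing <- setdiff(model$feature_genes, gene_ids(query))
  if (length(missing)) {
    stop("query is missing feature gene(s): ", paste(missing, collapse = ", "))
  }
  sub <- subset_matrix(query, genes = model$feature_genes)
  if (scaling == "query") {
    z <- zscale_genes(sub)$values
  } else {
    z <- sweep(sub$values, 1, model$scaling_stats$mean, "-")
    sds <- model$scaling_stats$sd
    sds[sds == 0] <- 1
    z <- sweep(z, 1, sds, "/")
  }
  votes <- stats::predict(model$model, newdata = t(z), type = "vote", norm.votes = TRUE)
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  if (!is.null(min_vote_share)) {
    share <- votes[cbind(seq_len(nrow(votes)), max.col(votes, ties.method = "first"))]
    pred[share < min_vote_share] <- NA_character_
  }
  stats::setNames(pred, cell_ids(query))
}

#' Six-metric one-vs-rest classification report
#'
#' For each class, one-vs-rest counts (TP, FP, TN, FN) yield accuracy,
#' sensitivity, specificity, PPV, NPV and F1; ratios with a zero denominator
#' are set to 0 and flagged. Macro values are unweighted means over classes.
#'
#' @param pred,truth Equal-length aligned label vectors.
#' @param classes Label universe (default: union of observed labels). Labels
#'   outside `classes` raise an error.
#' @return An object of class `MetricsReport`: `per_class` (data.frame),
#'   `macro` (named numeric), `confusion` (truth x prediction counts),
#'   `undefined` (data.frame of zero-denominator flags).
#' @export
evaluate <- function(pred, truth, classes = sort(unique(c(pred, truth)))) {
  if (length(pred) != length(truth)) stop("`pred` and `truth` lengths differ")
  bad <- setdiff(unique(c(pred, truth)), classes)
  if (length(bad)) stop("label(s) outside `classes`: ", paste(bad, collapse = ", "))
  n <- length(truth)
  confusion <- table(truth = factor(truth, classes), pred = factor(pred, classes))
  metric_names <- c("accuracy", "sensitivity", "specificity", "NPV", "PPV", "F1")
  per_class <- data.frame(class = classes)
  for (mn in metric_names) per_class[[mn]] <- NA_real_
  undefined <- data.frame(class = character(), metric = character())
  safe <- function(num, den, class, metric) {
    if (den == 0) {
      undefined <<- rbind(undefined, data.frame(class = class, metric = metric))
      return(0)
    }
    num / den
  }
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- n - tp - fp - fn
    sens <- safe(tp, tp + fn, cl, "sensitivity")
    spec <- safe(tn, tn + fp, cl, "specificity")
    ppv <- safe(tp, tp + fp, cl, "PPV")
    npv <- safe(tn, tn + fn, cl, "NPV")
    f1 <- safe(2 * ppv * sens, ppv + sens, cl, "F1")
    per_class[i, metric_names] <- c((tp + tn) / n, sens, spec, npv, ppv, f1)
  }
  macro <- colMeans(per_class[, metric_names, drop = FALSE])
  structure(list(per_class = per_class, macro = macro,
                 confusion = confusion, undefined = undefined),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport (macro over", nrow(x$per_class), "classes):\n")
  print(round(x$macro, 4))
  invisible(x)
}

#' Write a MetricsReport as TSV and JSON
#' @param report A `MetricsReport`.
#' @param path_prefix Files `<prefix>.tsv` and `<prefix>.json` are written.
#' @return Invisibly, the paths.
#' @export
write_metrics_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "MetricsReport"))
  tsv <- paste0(path_prefix, ".tsv")
  js <- paste0(path_prefix, ".json")
  utils::write.table(report$per_class, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_class = report$per_class,
                            macro = as.list(report$macro),
                            confusion = as.data.frame(report$confusion)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
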