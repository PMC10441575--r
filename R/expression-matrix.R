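#' Construct an ExpressionMatrix
#'
#' A genes-by-cells numeric matrix tagged with the processing layer it holds:
#' raw `counts`, `lognorm` (log-normalized) or `zscore` (per-gene Z-scaled)
#' values. Gene and cell identifiers are carried as dimnames and must be
#' unique.
#'
#' @param values Numeric matrix (or sparse `Matrix`), genes as rows, cells as
#'   columns. Must have rownames (gene ids) and colnames (cell ids).
#' @param layer One of `"counts"`, `"lognorm"`, `"zscore"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, layer = c("counts", "lognorm", "zscore")) {
  layer <- match.arg(layer)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene ids as rownames and cell ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate cell ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (layer == "counts" && length(values)) {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts layer must contain nonnegative integers")
    }
  }
  structure(list(values = values, layer = layer), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [layer: %s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and cell identifiers of an ExpressionMatrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by gene and/or cell ids
#'
#' @param m An `ExpressionMatrix`.
#' @param genes,cells Character vectors of ids to keep (default: all).
#'   Order of the result follows the requested order.
#' @return An `ExpressionMatrix` with the same layer.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) stop("genes not present: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(v))
    if (length(missing)) stop("cells not present: ", paste(missing, collapse = ", "))
    v <- v[, cells, drop = FALSE]
  }
  expression_matrix(v, m$layer)
}

#' Validate ExpressionMatrix layer invariants
#'
#' Checks the layer contract: counts are nonnegative integers; a zscore layer
#' has per-gene mean ~0 and unit sample standard deviation (within `tol`) for
#' non-constant genes.
#'
#' @param m An `ExpressionMatrix`.
#' @param tol Numeric tolerance for the zscore checks.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_expression_matrix <- function(m, tol = 1e-8) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer == "counts") {
    if (any(m$values < 0) || any(m$values != round(m$values))) {
      stop("counts layer must contain nonnegative integers")
    }
  } else if (m$layer == "zscore") {
    mu <- rowMeans(m$values)
    sds <- apply(m$values, 1, stats::sd)
    nonconst <- sds > tol
    if (any(abs(mu[nonconst]) > tol)) stop("zscore layer: per-gene means deviate from 0")
    if (any(abs(sds[nonconst] - 1) > tol)) stop("zscore layer: per-gene sds deviate from 1")
  }
  invisible(TRUE)
}

#' Construct a cell annotation table
#'
#' @param cell_id,dataset_id,label_original Character vectors of equal length.
#' @param label_medium Optional harmonized medium-level labels (`NA` until
#'   harmonization).
#' @return A `data.frame` with columns cell_id, dataset_id, label_original,
#'   label_medium.
#' @export
cell_annotation <- function(cell_id, dataset_id, label_original,
                            label_medium = NA_character_) {
  ann <- data.frame(cell_id = as.character(cell_id),
                    dataset_id = as.character(dataset_id),
                    label_original = as.character(label_original),
                    label_medium = as.character(label_medium),
                    stringsAsFactors = FALSE)
  dup <- ann$cell_id[duplicated(paste(ann$dataset_id, ann$cell_id))]
  if (length(dup)) stop("duplicate cell_id within dataset: ", paste(unique(dup), collapse = ", "))
  ann
}

#' Bundle per-dataset matrices and annotations into a DatasetCollection
#'
#' @param datasets Named list; each element a list with components `matrix`
#'   (an `ExpressionMatrix`) and `annotation` (a cell annotation data.frame
#'   whose cell_ids all exist in the matrix).
#' @param gene_universe Policy tag, `"intersection"` or `"union"`, recording
#'   how a shared gene universe is formed across datasets.
#' @return An object of class `DatasetCollection`.
#' @export
dataset_collection <- function(datasets, gene_universe = c("intersection", "union")) {
  gene_universe <- match.arg(gene_universe)
  if (!length(datasets)) stop("a DatasetCollection needs at least one dataset")
  if (is.null(names(datasets)) || anyDuplicated(names(datasets))) {
    stop("datasets must be uniquely named by dataset_id")
  }
  for (id in names(datasets)) {
    d <- datasets[[id]]
    if (!inherits(d$matrix, "ExpressionMatrix")) {
      stop("dataset ", id, ": missing ExpressionMatrix")
    }
    if (!all(d$annotation$cell_id %in% cell_ids(d$matrix))) {
      stop("dataset ", id, ": annotation refers to cells absent from the matrix")
    }
  }
  structure(list(datasets = datasets, gene_universe = gene_universe),
            class = "DatasetCollection")
}

#' @export
print.DatasetCollection <- function(x, ...) {
  cat(sprintf("DatasetCollection: %d dataset(s) [gene universe: %s]\n",
              length(x$datasets), x$gene_universe))
  for (id in names(x$datasets)) {
    m <- x$datasets[[id]]$matrix
    cat(sprintf("  %s: %d genes x %d cells [%s]\n", id,
                nrow(m$values), ncol(m$values), m$layer))
  }
  invisible(x)
}

#' Genes shared by every dataset of a collection
#' @param collection A `DatasetCollection`.
#' @return Character vector of common gene ids, in the order of the first
#'   dataset.
#' @export
common_genes <- function(collection) {
  stopifnot(inherits(collection, "DatasetCollection"))
  Reduce(intersect, lapply(collection$datasets, function(d) gene_ids(d$matrix)))
}

#' Construct a SignatureSet
#'
#' Ordered gene lists keyed by signature id, with an optional cell-type
#' annotation per signature.
#'
#' @param entries Named list of character vectors (non-empty, no duplicates
#'   within a list).
#' @param annotation Optional named character vector mapping signature ids to
#'   cell types.
#' @return An object of class `SignatureSet`.
#' @export
signature_set <- function(entries, annotation = NULL) {
  if (!length(entries)) {
    return(structure(list(entries = list(), annotation = NULL), class = "SignatureSet"))
  }
  if (is.null(names(entries)) || anyDuplicated(names(entries))) {
    stop("signature ids must be unique and non-empty")
  }
  for (id in names(entries)) {
    g <- entries[[id]]
    if (!length(g)) stop("signature ", id, ": empty gene list")
    if (anyDuplicated(g)) stop("signature ", id, ": duplicate genes")
  }
  if (!is.null(annotation)) {
    bad <- setdiff(names(annotation), names(entries))
    if (length(bad)) stop("annotation for unknown signature(s): ", paste(bad, collapse = ", "))
  }
  structure(list(entries = entries, annotation = annotation), class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet: %d signature(s)\n", length(x$entries)))
  for (id in names(x$entries)) {
    ann <- if (!is.null(x$annotation) && id %in% names(x$annotation)) {
      paste0(" [", x$annotation[[id]], "]")
    } else ""
    cat(sprintf("  %s%s: %d genes\n", id, ann, length(x$entries[[id]])))
  }
  invisible(x)
}

#' @export
length.SignatureSet <- function(x) length(x$entries)

#' All distinct genes in a SignatureSet
#' @param sig A `SignatureSet`.
#' @param exclude Signature ids to leave out.
#' @return Character vector (union, first-occurrence order).
#' @export
signature_genes <- function(sig, exclude = character()) {
  stopifnot(inherits(sig, "SignatureSet"))
  keep <- setdiff(names(sig$entries), exclude)
  unique(unlist(sig$entries[keep], use.names = FALSE))
}
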