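#' Read a gene-by-cell expression matrix from disk
#'
#' Supports the Matrix Market coordinate (triplet) format with plain-text
#' gene/cell id sidecar files (one id per line), and dense delimited tables
#' with a header row of cell ids and a first column of gene ids. Either way
#' the result is a counts-layer [expression_matrix()] preserving input order.
#'
#' @param path Path to the matrix file.
#' @param format `"mtx_triplet"` or `"delimited"`.
#' @param genes_path,cells_path Sidecar id files (mtx_triplet only). Default:
#'   `genes.tsv` and `cells.tsv` next to `path`.
#' @param sep Field separator for the delimited format (default tab).
#' @return An `ExpressionMatrix` with layer `"counts"`.
#' @export
read_expression <- function(path, format = c("mtx_triplet", "delimited"),
                            genes_path = file.path(dirname(path), "genes.tsv"),
                            cells_path = file.path(dirname(path), "cells.tsv"),
                            sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.size(path) == 0) stop("parse error in ", path, ": file is empty (line 1)")
  if (format == "mtx_triplet") {
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) stop("missing sidecar id file: ", p)
    }
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e))
    })
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (length(genes) != nrow(m)) {
      stop("gene sidecar has ", length(genes), " ids but matrix has ", nrow(m), " rows")
    }
    if (length(cells) != ncol(m)) {
      stop("cell sidecar has ", length(cells), " ids but matrix has ", ncol(m), " columns")
    }
    v <- as.matrix(m)
    dimnames(v) <- list(genes, cells)
    expression_matrix(v, "counts")
  } else {
    tab <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
    )
    v <- as.matrix(tab)
    if (!is.numeric(v)) {
      bad <- which(!apply(tab, 1, function(r) all(!is.na(suppressWarnings(as.numeric(r))))))[1]
      stop("parse error in ", path, ": non-numeric value near line ", bad + 1)
    }
    expression_matrix(v, "counts")
  }
}

#' Write an expression matrix as Matrix Market triplets with id sidecars
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output `.mtx` path; `genes.tsv`/`cells.tsv` sidecars are
#'   written next to it.
#' @return Invisibly, the paths written.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sm <- Matrix::Matrix(m$values, sparse = TRUE)
  Matrix::writeMM(sm, path)
  gp <- file.path(dirname(path), "genes.tsv")
  cp <- file.path(dirname(path), "cells.tsv")
  writeLines(gene_ids(m), gp)
  writeLines(cell_ids(m), cp)
  invisible(c(matrix = path, genes = gp, cells = cp))
}

#' Read / write per-cell annotation tables
#'
#' Tab-delimited with header columns `cell_id`, `dataset_id`, `label` (and
#' optionally `label_medium`).
#'
#' @param path File path.
#' @return For the reader, a cell annotation `data.frame` (see
#'   [cell_annotation()]).
#' @export
read_cell_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "dataset_id", "label")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  cell_annotation(tab$cell_id, tab$dataset_id, tab$label,
                  if ("label_medium" %in% names(tab)) tab$label_medium else NA_character_)
}

#' @rdname read_cell_annotations
#' @param ann Cell annotation `data.frame`.
#' @export
write_cell_annotations <- function(ann, path) {
  out <- data.frame(cell_id = ann$cell_id, dataset_id = ann$dataset_id,
                    label = ann$label_original, label_medium = ann$label_medium)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a signature table
#'
#' Tab-delimited with header; columns: signature id, comma-separated gene
#' list, optional cell-type annotation.
#'
#' @param path File path.
#' @return A `SignatureSet`.
#' @export
parse_signature_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("parse error in ", path, ": expected >= 2 columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate signature id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  entries <- list()
  for (i in seq_along(ids)) {
    raw <- tab[[2]][i]
    if (is.na(raw) || !nzchar(trimws(raw))) {
      stop("parse error in ", path, ": empty gene list for signature ", ids[i],
           " (line ", i + 1, ")")
    }
    genes <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      stop("parse error in ", path, ": empty gene list for signature ", ids[i],
           " (line ", i + 1, ")")
    }
    entries[[ids[i]]] <- genes
  }
  annotation <- NULL
  if (ncol(tab) >= 3) {
    annotation <- stats::setNames(as.character(tab[[3]]), ids)
    annotation <- annotation[!is.na(annotation) & nzchar(annotation)]
    if (!length(annotation)) annotation <- NULL
  }
  signature_set(entries, annotation)
}

#' @rdname parse_signature_table
#' @param sig A `SignatureSet`.
#' @export
write_signature_table <- function(sig, path) {
  stopifnot(inherits(sig, "SignatureSet"))
  ids <- names(sig$entries)
  out <- data.frame(
    signature_id = ids,
    genes = vapply(sig$entries, paste, character(1), collapse = ","),
    annotation = vapply(ids, function(id) {
      if (!is.null(sig$annotation) && id %in% names(sig$annotation)) {
        sig$annotation[[id]]
      } else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated genes. Used for
#' external gene sets (e.g. Hallmark collections) scored with
#' [mean_signature_score()].
#'
#' @param path File path.
#' @return A `SignatureSet` (descriptions discarded).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  entries <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("parse error in ", path, ": line ", i,
                                " has fewer than 3 fields")
    entries[[parts[1]]] <- unique(parts[-(1:2)])
  }
  signature_set(entries)
}

#' The packaged immune cell type signatures
#'
#' Eleven refined immune cell type gene signatures (B, DC, two macrophage,
#' mast, monocyte, NK, pDC, plasma, CD4+ T and CD8+ T) discovered from seven
#' integrated tumor-microenvironment scRNA-seq datasets, shipped as a
#' plain-text table.
#'
#' @return A `SignatureSet` of 11 signatures with cell-type annotations.
#' @export
immune_signatures <- function() {
  parse_signature_table(system.file("extdata", "immune_signatures.tsv",
                                    package = "immunosig", mustWork = TRUE))
}
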