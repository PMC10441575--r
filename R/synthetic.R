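#' Specify a multi-dataset scRNA-seq simulation
#'
#' Describes negative-binomial count data for several datasets sharing the
#' same cell types, with planted structure mirroring what signature discovery
#' must distinguish: cell-type-specific marker modules (genes co-elevated in
#' exactly one cell type), shared "program" modules (genes co-elevated across
#' several cell types, e.g. an interferon response, which the max-median
#' filter should reject), and per-dataset batch effects.
#'
#' Expected counts for gene g in cell c of dataset d with type t are
#' `L_c * f_gc` where `L_c` is a lognormal library size and `f_gc` the
#' per-cell normalized fraction proportional to
#' `exp(base_g + batch_dg + marker + program)`; marker/program terms are
#' natural-log elevations applied to module genes in their target types (and,
#' for programs, active datasets). Counts are drawn independently per gene
#' and cell given these means — module co-expression arises purely from the
#' shared mean shifts.
#'
#' @param n_datasets,n_celltypes,cells_per_type_per_dataset,n_genes Problem
#'   dimensions.
#' @param marker_modules Named list (one element per cell type, names
#'   `celltype1`, ...) of disjoint gene index vectors. Default: consecutive
#'   10-gene blocks, one per cell type.
#' @param program_modules List of program descriptors, each a list with
#'   `genes` (indices), `celltypes` (affected type names) and `datasets`
#'   (active dataset names). Default: one 10-gene module active in all
#'   datasets and in all but one cell type (a program active everywhere has
#'   no cross-cell variance after Z-scaling and would be invisible to
#'   gene-space clustering).
#' @param marker_effect,program_effect Log-fold elevations (natural log).
#' @param batch_sd Standard deviation of per-dataset per-gene log offsets.
#' @param nb_dispersion Negative-binomial size parameter.
#' @param libsize_logmean,libsize_logsd Lognormal library-size parameters.
#' @param seed Integer seed; the simulation is bit-reproducible given the
#'   design.
#' @return An object of class `SimulationDesign`.
#' @export
simulation_design <- function(n_datasets = 3, n_celltypes = 4,
                              cells_per_type_per_dataset = 200, n_genes = 300,
                              marker_modules = NULL, program_modules = NULL,
                              marker_effect = 1.5, program_effect = 1.5,
                              batch_sd = 0.3, nb_dispersion = 2,
                              libsize_logmean = log(5000), libsize_logsd = 0.3,
                              seed = 1L) {
  celltypes <- paste0("celltype", seq_len(n_celltypes))
  datasets <- paste0("dataset", seq_len(n_datasets))
  if (is.null(marker_modules)) {
    marker_modules <- stats::setNames(
      lapply(seq_len(n_celltypes), function(k) ((k - 1) * 10 + 1):(k * 10)),
      celltypes)
  }
  if (is.null(program_modules)) {
    # a program spanning most (not all) cell types: co-varying across cells,
    # hence clusterable in gene space, yet with max ~ median cell-type score
    start <- max(unlist(marker_modules)) + 1L
    affected <- celltypes[seq_len(max(2L, n_celltypes - 1L))]
    program_modules <- list(list(genes = start:(start + 9L),
                                 celltypes = affected, datasets = datasets))
  }
  d <- structure(list(
    n_datasets = as.integer(n_datasets), n_celltypes = as.integer(n_celltypes),
    cells_per_type_per_dataset = as.integer(cells_per_type_per_dataset),
    n_genes = as.integer(n_genes), celltypes = celltypes, dataset_ids = datasets,
    marker_modules = marker_modules, program_modules = program_modules,
    marker_effect = marker_effect, program_effect = program_effect,
    batch_sd = batch_sd, nb_dispersion = nb_dispersion,
    libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
    seed = as.integer(seed)), class = "SimulationDesign")
  validate_design(d)
  d
}

#' @rdname simulation_design
#' @param design A `SimulationDesign`.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  with(design, {
    if (n_datasets < 1 || n_celltypes < 1 || n_genes < 1 ||
        cells_per_type_per_dataset < 1) stop("design dimensions must be positive")
    if (marker_effect < 0 || program_effect < 0 || batch_sd < 0) {
      stop("effects and batch_sd must be >= 0")
    }
    idx <- unlist(marker_modules)
    if (anyDuplicated(idx)) stop("marker modules must be disjoint")
    all_idx <- c(idx, unlist(lapply(program_modules, `[[`, "genes")))
    if (length(all_idx) && (min(all_idx) < 1 || max(all_idx) > n_genes)) {
      stop("module gene indices out of range 1..n_genes")
    }
    bad <- setdiff(names(marker_modules), celltypes)
    if (length(bad)) stop("marker modules for unknown cell type(s): ",
                          paste(bad, collapse = ", "))
    for (p in program_modules) {
      if (length(setdiff(p$celltypes, celltypes)) ||
          length(setdiff(p$datasets, dataset_ids))) {
        stop("program module refers to unknown cell type or dataset")
      }
    }
  })
  invisible(TRUE)
}

#' Simulate a multi-dataset single-cell collection
#'
#' Draws counts from the model described in [simulation_design()]. One global
#' RNG stream is keyed by `design$seed`; per-dataset sub-seeds are derived
#' from it, so identical designs give bit-identical output.
#'
#' @param design A `SimulationDesign`.
#' @return List with `collection` (a counts-layer `DatasetCollection`, cells
#'   annotated with their true type), `truth` (the design) and `libsizes`
#'   (named list of the drawn per-cell library sizes, per dataset).
#' @export
simulate_collection <- function(design) {
  validate_design(design)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(design$seed)
  base <- stats::rnorm(design$n_genes, 0, 1)
  subseeds <- sample.int(.Machine$integer.max - 1L, design$n_datasets)

  genes <- sprintf("gene%04d", seq_len(design$n_genes))
  n_cells <- design$n_celltypes * design$cells_per_type_per_dataset

  # genes x celltypes matrix of marker + per-dataset program elevations
  marker_eta <- matrix(0, design$n_genes, design$n_celltypes,
                       dimnames = list(NULL, design$celltypes))
  for (ct in names(design$marker_modules)) {
    marker_eta[design$marker_modules[[ct]], ct] <- design$marker_effect
  }

  datasets <- list()
  libsizes <- list()
  for (j in seq_len(design$n_datasets)) {
    did <- design$dataset_ids[j]
    set.seed(subseeds[j])
    batch <- stats::rnorm(design$n_genes, 0, design$batch_sd)
    eta_ct <- marker_eta
    for (p in design$program_modules) {
      if (did %in% p$datasets) {
        eta_ct[p$genes, p$celltypes] <- eta_ct[p$genes, p$celltypes] + design$program_effect
      }
    }
    types <- rep(design$celltypes, each = design$cells_per_type_per_dataset)
    libsize <- stats::rlnorm(n_cells, design$libsize_logmean, design$libsize_logsd)
    eta <- base + batch + eta_ct[, types, drop = FALSE]
    expf <- exp(eta)
    frac <- sweep(expf, 2, colSums(expf), "/")
    mu <- sweep(frac, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(length(mu), size = design$nb_dispersion, mu = mu),
                     nrow = design$n_genes)
    cells <- sprintf("%s_cell%04d", did, seq_len(n_cells))
    dimnames(counts) <- list(genes, cells)
    datasets[[did]] <- list(
      matrix = expression_matrix(counts, "counts"),
      annotation = cell_annotation(cells, did, types)
    )
    libsizes[[did]] <- stats::setNames(libsize, cells)
  }
  list(collection = dataset_collection(datasets), truth = design,
       libsizes = libsizes)
}

#' Write / read a simulation design as a flat key-value config
#'
#' Scalar fields are written as `key = value` lines; module structure is
#' encoded as comma-separated index lists (`marker.<celltype> = i,j,...`;
#' `program<k>.genes/celltypes/datasets`).
#'
#' @param design A `SimulationDesign`.
#' @param path File path.
#' @return The reader returns a `SimulationDesign`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "SimulationDesign"))
  lines <- c(
    sprintf("n_datasets = %d", design$n_datasets),
    sprintf("n_celltypes = %d", design$n_celltypes),
    sprintf("cells_per_type_per_dataset = %d", design$cells_per_type_per_dataset),
    sprintf("n_genes = %d", design$n_genes),
    sprintf("marker_effect = %.17g", design$marker_effect),
    sprintf("program_effect = %.17g", design$program_effect),
    sprintf("batch_sd = %.17g", design$batch_sd),
    sprintf("nb_dispersion = %.17g", design$nb_dispersion),
    sprintf("libsize_logmean = %.17g", design$libsize_logmean),
    sprintf("libsize_logsd = %.17g", design$libsize_logsd),
    sprintf("seed = %d", design$seed),
    vapply(names(design$marker_modules), function(ct) {
      sprintf("marker.%s = %s", ct, paste(design$marker_modules[[ct]], collapse = ","))
    }, character(1)),
    unlist(lapply(seq_along(design$program_modules), function(k) {
      p <- design$program_modules[[k]]
      c(sprintf("program%d.genes = %s", k, paste(p$genes, collapse = ",")),
        sprintf("program%d.celltypes = %s", k, paste(p$celltypes, collapse = ",")),
        sprintf("program%d.datasets = %s", k, paste(p$datasets, collapse = ",")))
    }))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  kv <- read_keyvalue(path)
  num <- function(k, d) if (k %in% names(kv)) as.numeric(kv[[k]]) else d
  markers <- kv[grepl("^marker\\.", names(kv))]
  marker_modules <- if (length(markers)) {
    stats::setNames(lapply(markers, function(v) as.integer(strsplit(v, ",")[[1]])),
                    sub("^marker\\.", "", names(markers)))
  } else NULL
  prog_keys <- unique(sub("\\..*$", "", grep("^program[0-9]+\\.", names(kv), value = TRUE)))
  program_modules <- if (length(prog_keys)) {
    lapply(prog_keys, function(pk) list(
      genes = as.integer(strsplit(kv[[paste0(pk, ".genes")]], ",")[[1]]),
      celltypes = strsplit(kv[[paste0(pk, ".celltypes")]], ",")[[1]],
      datasets = strsplit(kv[[paste0(pk, ".datasets")]], ",")[[1]]))
  } else NULL
  simulation_design(
    n_datasets = num("n_datasets", 3), n_celltypes = num("n_celltypes", 4),
    cells_per_type_per_dataset = num("cells_per_type_per_dataset", 200),
    n_genes = num("n_genes", 300),
    marker_modules = marker_modules, program_modules = program_modules,
    marker_effect = num("marker_effect", 1.5),
    program_effect = num("program_effect", 1.5),
    batch_sd = num("batch_sd", 0.3), nb_dispersion = num("nb_dispersion", 2),
    libsize_logmean = num("libsize_logmean", log(5000)),
    libsize_logsd = num("libsize_logsd", 0.3),
    seed = as.integer(num("seed", 1)))
}
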