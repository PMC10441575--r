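#' Read and validate a pipeline run configuration
#'
#' Flat `key = value` text file. Unknown keys are rejected. Input keys:
#' either `design` (path to a simulation design config; data are simulated)
#' or paired `matrix.<dataset>` / `annotations.<dataset>` paths (Matrix
#' Market triplets with sidecars, see [read_expression()]). `out_dir` is
#' required. Stage parameters (with defaults matching the reference
#' workflow): `epsilon` (0.18, or the string `knee`), `min_pts` (10),
#' `top_k` (50), `delta` (0.6), `min_datasets` (3), `n_hvgs` (3000),
#' `n_neighbors` (15), `min_dist` (0.1), `min_genes_per_cell` (200),
#' `min_cells_per_gene` (3), `alpha` (0.01), `seed` (42), `classify`
#' (true/false), `train_dataset`, `query_dataset`, `train_fraction` (0.67),
#' `n_trees` (500).
#'
#' @param config Path to the config file, or a named list of the same keys.
#' @return Validated config as a named list of class `RunConfig`.
#' @export
read_run_config <- function(config) {
  kv <- if (is.character(config)) read_keyvalue(config) else as.list(config)
  known_scalar <- c("design", "out_dir", "seed", "n_hvgs", "n_neighbors",
                    "min_dist", "epsilon", "min_pts", "top_k", "delta",
                    "min_datasets", "min_genes_per_cell", "min_cells_per_gene",
                    "alpha", "classify", "train_dataset", "query_dataset",
                    "train_fraction", "n_trees")
  unknown <- names(kv)[!(names(kv) %in% known_scalar |
                         grepl("^(matrix|annotations)\\.", names(kv)))]
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(kv$out_dir)) stop("config must set out_dir")

  num <- function(k, d) if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else d
  cfg <- list(
    design = kv$design, out_dir = kv$out_dir,
    seed = as.integer(num("seed", 42)),
    n_hvgs = num("n_hvgs", 3000), n_neighbors = num("n_neighbors", 15),
    min_dist = num("min_dist", 0.1),
    epsilon = if (identical(kv$epsilon, "knee")) "knee" else num("epsilon", 0.18),
    min_pts = num("min_pts", 10), top_k = num("top_k", 50),
    delta = num("delta", 0.6), min_datasets = num("min_datasets", 3),
    min_genes_per_cell = num("min_genes_per_cell", 200),
    min_cells_per_gene = num("min_cells_per_gene", 3),
    alpha = num("alpha", 0.01),
    classify = isTRUE(as.logical(if (is.null(kv$classify)) "FALSE" else kv$classify)),
    train_dataset = kv$train_dataset, query_dataset = kv$query_dataset,
    train_fraction = num("train_fraction", 0.67),
    n_trees = as.integer(num("n_trees", 500)),
    matrices = kv[grepl("^matrix\\.", names(kv))],
    annotations = kv[grepl("^annotations\\.", names(kv))]
  )
  if (!identical(cfg$epsilon, "knee") && cfg$epsilon <= 0) {
    stop("epsilon must be positive (or the string 'knee')")
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (is.null(cfg$design) && !length(cfg$matrices)) {
    stop("config must provide either `design` or matrix.<dataset> inputs")
  }
  ds_m <- sub("^matrix\\.", "", names(cfg$matrices))
  ds_a <- sub("^annotations\\.", "", names(cfg$annotations))
  if (length(cfg$matrices) && !setequal(ds_m, ds_a)) {
    stop("matrix.* and annotations.* dataset ids do not match")
  }
  structure(cfg, class = "RunConfig")
}

#' Run the discovery (and optionally classification) pipeline from a config
#'
#' Executes the configured stages in order, writes every artifact as TSV
#' under `out_dir`, and records a `manifest.json` (inputs, parameters, seed,
#' package version, per-artifact paths, status). On stage failure the
#' manifest marks the failure, partial artifacts are retained, and the error
#' is re-raised.
#'
#' @param config Path to a config file, a named list, or a `RunConfig`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "immunosig",
    version = as.character(utils::packageVersion("immunosig")),
    seed = cfg$seed,
    parameters = cfg[c("n_hvgs", "n_neighbors", "min_dist", "epsilon", "min_pts",
                       "top_k", "delta", "min_datasets", "min_genes_per_cell",
                       "min_cells_per_gene", "alpha", "classify",
                       "train_fraction", "n_trees")],
    inputs = if (!is.null(cfg$design)) list(design = cfg$design) else
      c(cfg$matrices, cfg$annotations),
    artifacts = list(), status = "running")
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  fail <- function(e) {
    manifest$status <<- "failed"
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop(e)
  }
  artifacts <- list()
  tryCatch({
    # --- input stage: simulate or load
    collection <- if (!is.null(cfg$design)) {
      simulate_collection(read_design(cfg$design))$collection
    } else {
      ds <- sub("^matrix\\.", "", names(cfg$matrices))
      dataset_collection(stats::setNames(lapply(ds, function(id) {
        list(matrix = read_expression(cfg$matrices[[paste0("matrix.", id)]]),
             annotation = read_cell_annotations(cfg$annotations[[paste0("annotations.", id)]]))
      }), ds))
    }

    # --- discovery
    res <- discover_signatures(
      collection, n_hvgs = cfg$n_hvgs, seed = cfg$seed,
      n_neighbors = cfg$n_neighbors, min_dist = cfg$min_dist,
      epsilon = if (identical(cfg$epsilon, "knee")) NULL else cfg$epsilon,
      min_pts = cfg$min_pts, top_k = cfg$top_k, delta = cfg$delta,
      min_datasets = cfg$min_datasets,
      min_genes_per_cell = cfg$min_genes_per_cell,
      min_cells_per_gene = cfg$min_cells_per_gene)

    p <- function(f) file.path(cfg$out_dir, f)
    write_signature_table(res$signatures, p("signatures.tsv"))
    artifacts$signatures <- p("signatures.tsv")
    clust_tab <- data.frame(
      gene = res$clustering$gene_ids,
      cluster = res$clustering$labels,
      silhouette = unname(res$silhouettes$per_gene[res$clustering$gene_ids]))
    utils::write.table(clust_tab, p("clustering.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$clustering <- p("clustering.tsv")
    utils::write.table(res$funnel, p("funnel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$funnel <- p("funnel.tsv")
    utils::write.table(scores_long(res$scores), p("scores_long.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts$scores <- p("scores_long.tsv")
    manifest$epsilon_used <- res$epsilon

    # --- enrichment validation of annotated signatures
    if (!is.null(res$signatures$annotation)) {
      norm <- lapply(collection$datasets, function(d) {
        filt <- qc_filter(d$matrix, cfg$min_genes_per_cell, cfg$min_cells_per_gene)
        list(matrix = log_normalize(filt),
             annotation = d$annotation[d$annotation$cell_id %in% cell_ids(filt), ])
      })
      enr <- validate_signatures(dataset_collection(norm), res$signatures,
                                 alpha = cfg$alpha, min_datasets = cfg$min_datasets)
      enr$validated <- attr(enr, "validated")[enr$signature_id]
      utils::write.table(enr, p("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$enrichment <- p("enrichment.tsv")
    }

    # --- optional classification stage
    if (cfg$classify) {
      ids <- names(collection$datasets)
      train_id <- if (!is.null(cfg$train_dataset)) cfg$train_dataset else ids[1]
      query_id <- if (!is.null(cfg$query_dataset)) cfg$query_dataset else
        setdiff(ids, train_id)[1]
      get_lognorm <- function(id) {
        d <- collection$datasets[[id]]
        filt <- qc_filter(d$matrix, cfg$min_genes_per_cell, cfg$min_cells_per_gene)
        list(matrix = log_normalize(filt),
             annotation = d$annotation[d$annotation$cell_id %in% cell_ids(filt), ])
      }
      tr <- get_lognorm(train_id)
      ann <- tr$annotation
      ann$label_medium <- ann$label_original  # simulated labels are already medium-level
      sp <- split_train_test(cell_ids(tr$matrix), cfg$train_fraction, cfg$seed)
      model <- train_classifier(subset_matrix(tr$matrix, cells = sp$train),
                                ann, res$signatures,
                                n_trees = cfg$n_trees, seed = cfg$seed)
      qu <- if (!is.na(query_id) && !is.null(query_id)) get_lognorm(query_id) else
        list(matrix = subset_matrix(tr$matrix, cells = sp$test), annotation = ann)
      pred <- predict_cells(model, qu$matrix)
      truth <- qu$annotation$label_original[match(names(pred), qu$annotation$cell_id)]
      report <- evaluate(pred, truth, classes = model$classes)
      write_metrics_report(report, p("metrics"))
      artifacts$metrics <- p("metrics.json")
      pred_tab <- data.frame(cell_id = names(pred), predicted = unname(pred),
                             truth = truth)
      utils::write.table(pred_tab, p("predictions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts$predictions <- p("predictions.tsv")
    }

    manifest$artifacts <- artifacts
    manifest$status <- "ok"
    write_manifest()
  }, error = fail)
  invisible(artifacts)
}
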