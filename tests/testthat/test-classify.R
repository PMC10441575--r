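test_that("label harmonization maps, keeps or drops per policy", {
  ann <- cell_annotation(paste0("c", 1:3), "d",
                         c("CD14 Mono", "Platelet", "B naive"))
  out <- harmonize_labels(ann)                       # default: drop unmapped
  expect_equal(out$label_medium, c("Monocytes", "B"))
  expect_false("c2" %in% out$cell_id)
  kept <- harmonize_labels(ann, unmapped = "keep")
  expect_equal(kept$label_medium[2], "Platelet")
  expect_error(harmonize_labels(ann, unmapped = "error"), "Platelet")
  # empty map with keep policy passes labels through
  empty <- data.frame(original = character(), medium = character())
  thru <- harmonize_labels(ann, empty, unmapped = "keep")
  expect_equal(thru$label_medium, ann$label_original)
  dupmap <- data.frame(original = c("x", "x"), medium = c("A", "B"))
  expect_error(harmonize_labels(ann, dupmap), "not a function")
})

test_that("train/test split is reproducible, disjoint and 67:33 by default", {
  cells <- sprintf("c%03d", 1:100)
  sp <- split_train_test(cells, seed = 4L)
  expect_length(sp$train, 67)
  expect_length(sp$test, 33)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), cells)
  expect_identical(split_train_test(cells, seed = 4L), sp)
  expect_false(identical(split_train_test(cells, seed = 5L)$train, sp$train))
  expect_equal(lengths(split_train_test(letters[1:4], 0.5, seed = 1L)),
               c(train = 2L, test = 2L))
  expect_error(split_train_test("c1"), "at least 2")
  expect_error(split_train_test(cells, 1.2), "in \\(0, 1\\)")
})

test_that("metrics match hand-computed one-vs-rest values", {
  # perfect 2-class prediction
  r <- evaluate(c("A", "B", "A"), c("A", "B", "A"))
  expect_true(all(unlist(r$per_class[, -1]) == 1))
  expect_true(all(r$macro == 1))

  # 3-class confusion [[8,1,1],[0,9,1],[2,0,8]] (rows = truth)
  truth <- rep(c("x", "y", "z"), each = 10)
  pred <- c(rep("x", 8), "y", "z",
            rep("y", 9), "z",
            "x", "x", rep("z", 8))
  r2 <- evaluate(pred, truth, classes = c("x", "y", "z"))
  expect_equal(unname(r2$confusion["x", ]), c(8, 1, 1))
  expect_equal(r2$per_class$sensitivity[1], 0.8)
  want <- oracle_metrics(pred, truth, c("x", "y", "z"))
  for (cl in c("x", "y", "z")) {
    got <- unlist(r2$per_class[r2$per_class$class == cl,
                               c("accuracy", "sensitivity", "specificity",
                                 "NPV", "PPV", "F1")])
    expect_equal(unname(got), unname(want[[cl]][names(got)]))
  }

  # constant predictor: predicted class has sensitivity 1, others 0
  r3 <- evaluate(rep("x", 30), truth, classes = c("x", "y", "z"))
  expect_equal(r3$per_class$sensitivity, c(1, 0, 0))
  expect_true(nrow(r3$undefined) > 0)   # PPV undefined for unpredicted classes
  expect_error(evaluate(c("A", "Q"), c("A", "A"), classes = "A"), "outside")
})

test_that("metrics agree with the counting oracle on random label vectors", {
  set.seed(6)
  classes <- c("a", "b", "c", "d")
  for (i in 1:100) {
    n <- sample(10:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    r <- evaluate(pred, truth, classes)
    want <- oracle_metrics(pred, truth, classes)
    for (cl in classes) {
      got <- unlist(r$per_class[r$per_class$class == cl, -1])
      expect_equal(unname(got), unname(want[[cl]][names(got)]), tolerance = 1e-12)
    }
    expect_equal(unname(r$macro),
                 unname(colMeans(do.call(rbind, want))), tolerance = 1e-12)
  }
})

test_that("macro metrics are invariant under consistent class relabeling", {
  set.seed(14)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  r1 <- evaluate(pred, truth, c("a", "b", "c"))
  swap <- function(x) ifelse(x == "a", "b", ifelse(x == "b", "a", x))
  r2 <- evaluate(swap(pred), swap(truth), c("a", "b", "c"))
  expect_equal(sort(unname(r1$macro)), sort(unname(r2$macro)))
})

# shared small training scenario for the classifier tests
sim_train <- local({
  design <- simulation_design(n_datasets = 2, n_celltypes = 4,
                              cells_per_type_per_dataset = 80, n_genes = 150,
                              seed = 41L)
  sim <- simulate_collection(design)
  prep <- lapply(sim$collection$datasets, function(d) {
    m <- log_normalize(qc_filter(d$matrix, 50, 3))
    ann <- d$annotation[d$annotation$cell_id %in% cell_ids(m), ]
    ann$label_medium <- ann$label_original
    list(matrix = m, annotation = ann)
  })
  genes <- sprintf("gene%04d", seq_len(design$n_genes))
  sig <- signature_set(lapply(setNames(design$marker_modules,
                                       paste0("S_", seq_along(design$marker_modules))),
                              function(i) genes[i]))
  list(prep = prep, sig = sig, design = design)
})

test_that("random forest training uses common signature genes and is seeded", {
  tr <- sim_train$prep$dataset1
  model <- train_classifier(tr$matrix, tr$annotation, sim_train$sig,
                            n_trees = 100, seed = 2L)
  expect_s3_class(model, "TrainedClassifier")
  expect_setequal(model$feature_genes,
                  intersect(signature_genes(sim_train$sig), gene_ids(tr$matrix)))
  # out-of-bag error is low on well-separated synthetic types
  oob <- model$model$err.rate[model$model$ntree, "OOB"]
  expect_lt(oob, 0.1)
  # restricting query genes shrinks the feature set to the intersection
  half <- model$feature_genes[1:15]
  m2 <- train_classifier(tr$matrix, tr$annotation, sim_train$sig,
                         query_genes = half, n_trees = 20, seed = 2L)
  expect_setequal(m2$feature_genes, half)
  expect_error(train_classifier(tr$matrix, tr$annotation, sim_train$sig,
                                query_genes = "nope", seed = 1L), "no common")
  # single tree with fixed seed is reproducible
  m3a <- train_classifier(tr$matrix, tr$annotation, sim_train$sig,
                          n_trees = 1, seed = 9L)
  m3b <- train_classifier(tr$matrix, tr$annotation, sim_train$sig,
                          n_trees = 1, seed = 9L)
  expect_identical(predict_cells(m3a, tr$matrix), predict_cells(m3b, tr$matrix))
})

test_that("prediction is consistent, errors on missing features, and generalizes", {
  tr <- sim_train$prep$dataset1
  qu <- sim_train$prep$dataset2
  ann <- tr$annotation
  sp <- split_train_test(cell_ids(tr$matrix), seed = 3L)
  model <- train_classifier(subset_matrix(tr$matrix, cells = sp$train),
                            ann, sim_train$sig, n_trees = 200, seed = 3L)
  # training cells are fit at least as well as held-out cells
  pred_tr <- predict_cells(model, subset_matrix(tr$matrix, cells = sp$train))
  pred_te <- predict_cells(model, subset_matrix(tr$matrix, cells = sp$test))
  acc <- function(p) {
    mean(p == ann$label_medium[match(names(p), ann$cell_id)])
  }
  expect_gte(acc(pred_tr), acc(pred_te))
  # a duplicated query cell gets an identical prediction
  dup <- tr$matrix$values[, c(sp$test[1], sp$test[1])]
  colnames(dup) <- c("cellA", "cellB")
  pd <- predict_cells(model, expression_matrix(dup, "lognorm"))
  expect_equal(unname(pd["cellA"]), unname(pd["cellB"]))
  # held-out dataset from a different batch is classified well
  pred_q <- predict_cells(model, qu$matrix)
  truth_q <- qu$annotation$label_medium[match(names(pred_q), qu$annotation$cell_id)]
  rep_q <- evaluate(pred_q, truth_q, classes = model$classes)
  expect_gt(rep_q$macro[["F1"]], 0.9)
  # missing feature gene is a hard error naming the gene
  qm <- subset_matrix(qu$matrix, genes = setdiff(gene_ids(qu$matrix),
                                                model$feature_genes[1]))
  expect_error(predict_cells(model, qm), model$feature_genes[1])
  # train-statistics scaling mode also works
  pred_alt <- predict_cells(model, qu$matrix, scaling = "train")
  expect_gt(mean(pred_alt == truth_q), 0.8)
})
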