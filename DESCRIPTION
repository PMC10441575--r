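Package: immunosig
Title: Immune Cell Type Signature Discovery and Random Forest Cell
    Classification for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers immune cell type gene expression signatures from
    multiple integrated single-cell RNA-seq datasets by clustering genes in a
    two-dimensional UMAP embedding of Z-scaled expression profiles with
    DBSCAN, refining the resulting gene clusters through silhouette-based
    filters and a max-median expression-score filter that rejects shared
    transcriptional programs, annotating signatures by cross-dataset majority
    of cell-type score maxima, and validating them with Wilcoxon rank-sum
    enrichment tests. Ships eleven published immune cell type signatures, a
    random forest cell-type classifier trained on signature genes with
    six-metric benchmarking, and a negative-binomial multi-dataset simulator
    with planted marker modules, program modules and batch effects for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    randomForest,
    uwot,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
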