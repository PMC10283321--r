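Package: germgrad
Title: Spatial Expression Gradients in the Drosophila Germarium from Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of single-cell RNA-seq UMI counts from
    somatic cells of the Drosophila germarium (escort cells, follicle stem
    cells and early follicle cells). Provides quality-control filters,
    per-cluster expression profiles normalized to a fixed total, a
    pseudocounted log2 enrichment score for marker-gene ranking, a
    fractional-change quartile classifier of expression gradients along the
    anterior-posterior axis with structural and empirical independence
    nulls, proportion-based assignment of expression clusters to anatomical
    cell types, and a negative-binomial synthetic germarium generator with
    known ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
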