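Package: gliakit
Title: Quantification Pipelines for Cortical Glia Single-Cell and Histology Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification machinery
    used in single-cell studies of cortical glia in the SOD1(G93A) mouse model
    of ALS: droplet pre-filtering, per-cell QC metrics, Xist/Y-based sex
    assignment, cell-type quality gates, gene-signature module scoring,
    log-normalization, PCA, graph clustering, marker detection, differential
    expression, pseudobulk construction and PCA, preranked gene-set enrichment
    with the weighted Kolmogorov-Smirnov statistic, and the accompanying
    histological quantifications (Yen thresholding with integrated density,
    Sholl profiling of microglia, brightest-substack myelin volume fraction,
    and nuclear marker co-localization counts). Ships synthetic-data
    generators with planted ground truth so every stage can be validated
    against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust
Config/testthat/edition: 3
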