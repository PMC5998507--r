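Package: teboot
Title: Weighted Bootstrap Analysis of Transposable Element Associated Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests for association between transposable element (TE) insertions and
    gene expression across species and tissues. Genes (plus 1 kb flanks) are
    intersected with age-classified TE annotations (species-specific insertions at
    >= 94 percent identity versus older insertions), and expression differences
    between genes carrying a focal TE class and matched reference genes are
    estimated by a weighted bootstrap in which reference genes are resampled with
    weights that match the test set's TE-composition and gene-length-bin
    distribution. Confidence intervals control the family-wise error rate at
    level 1 - alpha/m across m = tissues x elements tests, with zero-crossing
    p-values and Benjamini-Hochberg FDR. Includes a synthetic-data generator with
    planted expression effects, expression-based sample clustering (UPGMA,
    Ward.D2, PCA), and a significance heatmap of results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
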