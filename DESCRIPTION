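Package: noremod
Title: Multi-Omic Analysis of Nitric Oxide Dependent Remodeling in Macrophages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for identifying nitric oxide (NO)-dependent
    proteomic and transcriptomic remodeling in classically activated
    macrophages. Provides a synthetic-data generator for coupled factorial
    proteome/transcriptome experiments with planted regulatory classes;
    preprocessing of intensity matrices (channel normalization, valid-value
    filtering, down-shifted normal imputation, log2 and z-score transforms);
    per-feature differential statistics (Welch t-tests on intensities, a
    simplified negative-binomial Wald test on counts, Benjamini-Hochberg
    adjustment); PCA-based contributor selection and a four-way z-score
    classifier of NO dependence; cross-model and cross-omic fold-change
    concordance with strong-responder quadrants and triple-concordance
    ranking; and local hypergeometric gene-set over-representation over GMT
    libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    rlang,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pheatmap,
    optparse
Config/testthat/edition: 3
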