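Package: epitrait
Title: Epigenome-Based Estimation of Plant Traits from CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to estimate plant traits from whole-genome bisulphite
    sequencing methylomes. Reads per-cytosine CpG reports, merges
    strand-symmetric CpG dyads, applies coverage filtering and train/test
    separated mean imputation, selects features by per-CpG Welch's t-tests
    with Benjamini-Hochberg FDR control, and fits regularized
    two-hidden-layer feed-forward neural networks with stochastic gradient
    descent and sevenfold cross-validation. Fitted models are interpreted
    through weight-based (Gedeon) variable importance, backward feature
    elimination, and Profile-method methylation-response curves. A
    synthetic methylome generator with planted tissue, provenance and
    quantitative-trait effects supports end-to-end validation of the
    pipeline without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
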