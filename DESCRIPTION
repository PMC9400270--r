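Package: evlfq
Title: Differential Abundance Analysis of Co-Culture Extracellular Vesicle
    Proteomes from Label-Free Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free quantification (LFQ) protein
    abundance matrices from multi-condition secretome or extracellular-vesicle
    experiments. Implements detection filtering, log2 transformation,
    downshifted-Gaussian imputation of values missing not at random,
    asymmetric quartile width-adjustment normalization, per-protein one-way
    ANOVA with Benjamini-Hochberg false discovery rate control, hierarchical
    clustering of significant expression profiles, and pattern-based candidate
    ranking for proteins elevated in a co-culture (interaction) condition.
    Includes a synthetic-data generator with known ground truth,
    identification-set Venn accounting, and overlap reporting against
    extracellular-vesicle reference compendia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
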