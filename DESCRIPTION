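Package: ssgwas
Title: Single-Step GWAS Window Variance and Its Stability Across Generations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for single-step genomic BLUP
    (ssGBLUP) association studies in selected livestock populations. Simulates
    multi-generation populations under truncation selection with a mixed
    polygenic and moderate-QTL architecture, applies marker quality control,
    builds pedigree (A), genomic (G) and combined (H) relationship matrices,
    solves multi-trait mixed model equations for genomic breeding values,
    back-solves SNP marker effects with iterative variance weighting, decomposes
    additive variance into exclusive SNP windows, and quantifies how the top
    windows persist across sliding generation subsets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
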