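Package: allelemix
Title: Allele-Specific Expression in Spatial Transcriptomics with Cell-Type Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) in spatial
    transcriptomics while accounting for cell-type mixtures at each
    measurement spot. Maternal allele counts are modelled with a
    beta-binomial generalized linear model whose mean is a cell-type
    weighted mixture of inverse-logit linear predictors; per-gene maximum
    likelihood fits use a second-order trust-region optimizer with an
    alternating overdispersion step. Includes a self-contained 2D
    thin-plate regression spline basis for non-parametric spatial
    surfaces, a four-category hypothesis testing suite with
    Benjamini-Hochberg correction, surface and cross-section estimation
    with pointwise confidence intervals, and a simulation framework for
    validating surface recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    parallel,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
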