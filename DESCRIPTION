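Package: cfabattery
Title: Confirmatory Factor Models for Cognitive Test Battery Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood confirmatory factor analysis of pooled
    correlation matrices from cognitive test batteries. Fits hierarchical,
    oblique, nested (bifactor-style) and full orthogonal factor models to a
    correlation matrix analyzed as a covariance matrix, computes the classic
    fit indices (chi-squared, GFI, AGFI, CFI, RMSEA and the legacy CALIS
    Akaike variant), performs stepwise model modification driven by
    Lagrange-multiplier and Wald projections, and cross-validates fitted
    loadings to new population samples with only the uniquenesses
    re-estimated. Includes Fisher-z pooling of correlation tables, a catalog
    of published Wechsler Adult Intelligence Scale (WAIS-IV) structural
    models, and a synthetic-data generator producing WAIS-like
    multi-population surrogate batteries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
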