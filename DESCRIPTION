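Package: genHawkes
Title: Multivariate Hawkes Process Models for Genomic Point Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the joint occurrences of transcriptional regulatory
    elements (TREs) along chromosomes as a multivariate nonlinear Hawkes
    point process. Enriched regions from ChIP-chip/ChIP-seq experiments are
    reduced to midpoint proxies; the conditional intensity of each mark is
    log-linear in indicator covariates and in cubic B-spline transfer
    functions of the distances to upstream occurrences of every mark.
    Provides exact likelihood computation on a sparse discretized design,
    maximum-likelihood estimation with analytic derivatives, pointwise
    confidence bands for the multiplicative g-functions, likelihood-ratio
    tests of local independence with Holm correction, Ward clustering of
    interaction weights, and exact simulation by Ogata thinning with a
    linear intensity cap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    splines,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
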