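Package: nlmrbias
Title: Stratified Non-Linear Mendelian Randomization with Bias Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-sample Mendelian randomization on exposure strata built by the
    residual and the doubly-ranked stratification methods, together with the
    bias-detection toolkit used to audit such analyses: negative-control-outcome
    analysis, Cochran's Q heterogeneity and inverse-variance-weighted trend tests
    across strata, pooling of doubly-ranked replicates by Rubin's rules, a check
    of the constant genetic effect assumption via per-stratum instrument-exposure
    associations, and a repeat-measurement strata-stability (transition matrix)
    analysis. Includes a synthetic cohort generator with a polygenic instrument,
    confounding, negative-control outcomes and configurable selection into the
    analysed sample, so that the collider/selection mechanisms that produce
    spurious stratum-specific estimates can be studied without individual-level
    biobank data, plus a minimal weighted-allele-score builder and delimited-text
    cohort I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
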