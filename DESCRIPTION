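Package: repmix
Title: Reproducibility Analysis of Replicate High-Throughput Studies via
    Constrained Gaussian Mixtures
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies reproducible targets across two replicate
    high-throughput studies (e.g. microarray comparisons of a treatment
    and a control group) by modelling the paired per-gene test statistics
    as a three-component bivariate Gaussian mixture: a zero-mean
    irreproducible component and two reproducible components for
    consistently up- and down-regulated targets, with structured
    covariances driven by a shared between-study variance. Parameters are
    estimated by an EM algorithm with multiple random restarts, and each
    target is scored by its posterior null probability (a local false
    discovery rate). Includes two-sample t-statistic computation from
    expression matrices, a max-p partial-conjunction baseline, a
    sign-discordance diagnostic, and a simulation harness that evaluates
    sensitivity, specificity and misclassification against generative
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
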