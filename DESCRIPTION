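Package: rtfmod
Title: Retarded Transient Function Modelling of Time-Course Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the retarded transient function (RTF), a phenomenological
    model of cellular signalling dynamics composed of a sustained and a
    transient component evaluated on a nonlinearly transformed, delayed time
    axis. Supports single-dose and dose-dependent (Hill-parameterized) fits
    by maximum likelihood with analytic gradients and multi-start bounded
    optimization, stepwise model reduction via likelihood-ratio tests, a
    synthetic time-course generator, and a low-dimensional embedding of
    fitted parameters across many time courses for comparing dynamics
    between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs,
    cluster,
    vegan,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
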