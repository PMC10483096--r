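Package: hoiscan
Title: Detecting Higher-Order Species Interactions in Microcosm Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers pairwise and higher-order interaction (HOI) strengths
    between competing protist species from abundance time series of
    laboratory microcosms. Converts density series into per-capita growth
    rate observations, fits a suite of six discrete-time competition models
    (additive and interactive Lotka-Volterra with intraspecific,
    interspecific or full HOI terms, and additive/interactive Ricker models)
    by Gaussian maximum likelihood with identity or log links, ranks them by
    small-sample-corrected AICc with a parsimony rule, and quantifies
    species persistence via Kaplan-Meier survival curves with log-rank
    comparisons. Includes a stochastic community simulator emulating the
    six-treatment, 24-microcosm experimental design so the entire pipeline
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    MASS,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
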