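Package: gfresponse
Title: Growth-Factor Signaling Response Analysis for Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for immediate-early growth-factor signaling
    measured across panels of cancer cell lines: log-domain replicate
    averaging, two-standard-deviation significance calls, maximal fold-change
    summaries, k-means kinetic classification of pERK/pAKT time courses,
    dose-sensitivity classification by the 75 percent rule, Cramer-von Mises
    fitting of the pAKT/pERK pathway scale factor, arctangent pathway-bias
    angles, correlation and rank-sum enrichment panels against basal receptor
    tyrosine kinase profiles, and node-edge signaling graphs with subtype
    aggregates. Includes a synthetic-data generator with planted ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
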