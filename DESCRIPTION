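Package: ropeteam
Title: Simplicial Analysis of Co-Climbing Relationships and Expedition Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted simplicial complexes from joint-expedition
    histories of mountaineering cohorts and relates the topology of
    pre-existing group relationships to individual and expedition-level
    success. Provides per-climber influence (maximal simplicial dimension),
    weight filtrations over a persistence-style threshold, repeated-partner
    failure-ratio analysis, polarized-versus-cooperative expedition style
    classification, bipartite climber-feature projections with eigenvector
    centrality, and expedition-wide factor correlations, together with a
    synthetic cohort generator with planted effects so every stage is
    testable without access to external expedition databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
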