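Package: nutriconnect
Title: Connectivity Mapping of Diet-Disease Associations from Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores diet-disease and drug-disease associations from genome-wide
    expression signatures by a Kolmogorov-Smirnov signature-reversal enrichment
    score over rank-product meta-analytic differential expression, characterizes
    the associations by pathway-level principal component analysis and
    interactome closest-distance proximity with degree-matched null models, and
    predicts synergistic food pairs with directional-overlap, correlation and
    rank-aggregation scores against a literature-count gold standard. Includes a
    synthetic-data generator that plants known signature reversals, network
    modules and synergy pairs so the whole pipeline can be exercised and
    validated end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
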