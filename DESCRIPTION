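Package: aopnet
Title: Construction and Topological Analysis of Adverse Outcome Pathway Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assemble directed Adverse Outcome Pathway (AOP) networks
    from AOP-Wiki style exports and to characterise them topologically.
    Covers keyword screening of candidate pathways, expert-driven key event
    harmonisation, directed network assembly with adjacency and evidence
    attributes, per-node centrality metrics (degree, betweenness, stress,
    out-eccentricity, combined importance, convergent/divergent flow
    classification, MIE-to-AO simple-path occurrence), evidence and
    quantitative-understanding recoding, key characteristic and detection
    method annotation, and export to SIF, GraphML and categorical overlay
    formats. Includes a seeded synthetic fixture generator emulating
    AOP-Wiki collections for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    tibble,
    xml2,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
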