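Package: kinsel
Title: Selectivity Scoring and Ranking for Kinase Inhibitor Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing wide-format compound-by-kinase inhibition
    matrices from large-scale kinase inhibitor screens. Computes a composite
    selectivity score that combines on-target inhibition (a geometric mean over
    a chosen target set) with two threshold-free off-target penalties, one for
    broad weak inhibition and one for off-targets close in magnitude to the
    target. Ranks compounds for a chosen set of up to ten target kinases,
    reports significant off-targets, standardizes kinase names across panels,
    summarizes dataset coverage, renders black-yellow-red inhibition heatmaps,
    and generates synthetic screen matrices for testing. Includes comparison
    metrics (Gini coefficient, S(x) score) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
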