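Package: concycle
Title: Concurrent Cell-Cycle Processes and Division Control in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of bacterial cell-division control from mother-machine
    lineage data. Implements the adder coupling-constant formalism relating
    adder-plot slopes (zeta) to size-growth-plot slopes (lambda), closed-form
    correlation predictions for replication-limited (ICD), inter-initiation /
    C+D adder (Witz-type) and concurrent-cycles (AND-gate) models of division
    control, stochastic forward simulators of single-cell lineages, robust
    estimation of adder slopes over the inter-division, inter-initiation and
    C+D subperiods, detection of replication rounds (C and D periods) from
    per-frame replisome-signal traces, fitting of the limiting probability pH
    of the replication-independent inter-division process, and a synthetic
    mother-machine data generator including an in-silico analogue of the A22
    width-perturbation series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    MASS,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
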