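Package: ciplvnet
Title: EEG Phase-Synchronization and Brain-Network Analysis for Group Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for sensor-space EEG functional connectivity
    studies with two-group designs: corrected imaginary phase locking value
    (ciPLV) connectivity per frequency band, weighted graph metrics (global and
    nodal efficiency, Onnela clustering coefficient, Louvain modularity with an
    exact per-node decomposition), cluster-level permutation tests in edge and
    sensor space, Go/No-Go signal-detection scoring (d-prime with perfect-score
    adjustment), and cohort statistics. Includes a synthetic-data module that
    generates multichannel EEG epochs with known phase-lagged coupling between
    chosen channel pairs, Go/No-Go behavior with set hit and false-alarm rates,
    and cohort tables, so the full analysis chain can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
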