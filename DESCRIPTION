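Package: connstate
Title: Two-Condition Functional Connectome Analysis with Network-Based
    Statistics and Graph Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for paired two-condition resting-state
    functional connectivity studies: framewise-displacement motion summaries,
    nuisance regression and band-pass filtering of ROI timeseries, Pearson
    connectivity matrices, network-based statistics (NBS) with sign-flip
    permutation family-wise error control, graph-theoretic characterisation
    (betweenness, transitivity, assortativity, global efficiency,
    small-worldness against degree-preserving rewired nulls) aggregated as
    areas under the cost curve with permutation tests and FDR correction,
    and covariate correlation with mean component connectivity.  Includes a
    seeded synthetic-data generator with planted condition and covariate
    effects for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
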