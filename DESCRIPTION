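Package: boolsynth
Title: Synthesis of Dominant-Inhibition Boolean Networks by Monte Carlo Tree Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic construction of Boolean logic models of gene regulation
    whose simulated attractors match reference steady-state data. Models are
    restricted to dominant-inhibition update rules and are built one signed
    interaction at a time by Monte Carlo tree search (UCT with RAVE value
    sharing, nested-search commitment and branch retention). Includes a
    synchronous simulator with cyclic-attractor averaging, a greedy attractor
    edit distance for scoring, constraint-based action-space enumeration with
    multicellular tiling, random-model benchmarks, and a multi-model analysis
    toolkit (Jaccard clustering, common and distinguishing interaction sets,
    in-silico knockout disruption ranking). Ships a four-cell Drosophila
    segment polarity network fixture with wild-type and knockout conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
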