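Package: triadnet
Title: Generating Directed Networks with Prescribed Blockmodel Structures
    from Triad Types
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for studying how global
    network structures emerge from local triadic constraints. Builds ideal
    blockmodel networks (cohesive, core-periphery, hierarchical,
    transitivity) under structural equivalence, computes the 16-type
    directed triad census with incremental change statistics, generates
    networks whose triad composition matches a target with a deterministic
    relocating-links algorithm or a fixed-coefficient exponential random
    graph Metropolis-Hastings sampler, fits pre-specified blockmodels with
    a relocation search, and scores generated networks with the mean
    improvement value against density-matched random networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
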