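Package: fasnet
Title: Associative-Memory Deterioration in Hopfield Networks with Focal
    Axonal Swellings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-state Hopfield associative-memory networks in
    which a fraction of neurons carries focal axonal swellings (FAS). Swollen
    axons transmit, filter, reflect or block the spike trains they carry; the
    package samples per-neuron injury regimes from experimentally motivated
    mixtures (pie-charts), runs stochastic recall trials on noisy cues, scores
    recognition outcomes (correct recall, non-convergence, confusion), sweeps
    noise-by-injury grids, and fits exponential deterioration laws
    R(p) = A - B*exp(p) to the resulting recognition scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
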