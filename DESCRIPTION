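Package: critmem
Title: Criticality-Mediated Memory Consolidation in Attractor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how proximity to a dynamical critical point shapes
    the storage of new memories in Hopfield-type attractor networks, and to
    assess critical dynamics in spike-train recordings. Implements directed
    small-world network construction with Hebbian pattern embedding,
    stochastic heat-bath state dynamics with external-input protocols,
    state-based plasticity and consolidation experiments, critical-temperature
    estimation from order-parameter curves, multistep-regression branching
    parameter estimation with stationarity screening, and generators for
    synthetic spike-train cohorts that emulate slow-wave-sleep recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
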