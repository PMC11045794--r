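Package: NeuroIsing
Title: Maximum-Entropy Ising Analysis of Critical Integrate-and-Fire Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates spontaneous activity of plastic integrate-and-fire
    neuronal networks on spatially embedded scale-free graphs, tunes the
    short-term-plasticity recovery parameter to the critical (neuronal
    avalanche) state, and maps the binarized firing statistics onto pairwise
    Ising models by Boltzmann-machine maximum-entropy learning. Provides
    Metropolis Monte Carlo and exact-enumeration samplers, thermodynamic
    temperature sweeps (magnetization, susceptibility, specific heat),
    coupling pruning for partially-connected models, subnetwork selection,
    discrete power-law fitting for avalanche statistics, and synthetic
    spin-raster generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
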