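Package: boolmotifs
Title: Stable-Motif Analysis, Attractor Control and Phenotype Landscapes
    for Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asynchronous Boolean network dynamics applied to
    cell-fate decisions such as the TGF-beta-driven epithelial-to-mesenchymal
    transition (EMT). Implements stochastic asynchronous simulation with a
    percentage-of-transition readout, systematic single and combinatorial
    knockout/constitutive-activation screens, stable-motif identification via
    the prime-implicant expanded network, succession diagrams and attractor
    enumeration, stable-motif control sets that drive any initial condition to
    a target attractor, and quantitative placement of steady states on an
    epithelial/mesenchymal spectrum by biorthogonal pattern projection,
    principal component analysis and hierarchical clustering. Ships a small
    synthetic EMT-like demonstration network and brute-force oracles so every
    stage is testable on networks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
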