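Package: meiolandmark
Title: Landmark Analysis of Meiotic Progression from Live-Cell Imaging
    Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse categorical per-cell time series of meiotic
    morphology from live-cell imaging of Arabidopsis male meiocytes. Five
    ordered morphological parameters (cell shape, microtubule array, nucleus
    position, nucleolus position, chromatin/REC8 pattern) define a discrete
    cellular state per cell per frame. The package enumerates observed
    cellular states, computes the neighboring score that identifies landmark
    states (convergence points of meiotic progression), quantifies pairwise
    parameter-state co-occurrence with missing-aware column normalisation,
    assesses score stability by bootstrap resampling, builds the observed
    directed transition network, and extracts per-landmark durations and
    meiotic timelines from landmark-labelled trajectories. A seeded synthetic
    trajectory generator with planted ground truth makes every stage testable
    without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
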