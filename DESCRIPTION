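Package: phyloendemism
Title: Spatial Phylogenetic Endemism, CANAPE Classification, and Hotspot Driver Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for range-weighted spatial phylogenetics on gridded
    species occurrence data. Computes phylogenetic endemism (PE) on an
    original phylogeny and on an equal-branch-length comparison phylogeny,
    their ratio (relative phylogenetic endemism, RPE), and classifies grid
    cells into centres of neo-, paleo-, and mixed endemism with the CANAPE
    tip-shuffling randomization test. Downstream analyses cover driver
    regression with ordinary least squares and maximum-likelihood spatial
    simultaneous autoregressive (SAR) error models on k-nearest-neighbour
    weights, Moran's I diagnostics, Fisher-Pitman permutation comparisons
    between hotspot classes, and protected-area / priority-area coverage
    accounting. A synthetic-data module generates birth-death phylogenies,
    spatially cohesive gridded ranges with planted refugia, autocorrelated
    environmental surfaces, and protection masks so the full pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
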