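Package: rwrsmooth
Title: Network Smoothing of Single-Cell Expression by Random Walks with
    Restarts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Smooths single-cell gene expression matrices over a prior
    gene-gene interaction network using a random-walk-with-restarts
    diffusion kernel, mitigating dropout noise by borrowing signal from
    network neighbours. Includes a robust consensus-clustering procedure
    (PAM over multiple reduced-dimension views, co-clustering consensus,
    differential-expression-based cluster merging), evaluation metrics
    (cluster purity, adjusted mutual information, 2D-embedding grid
    entropy), data-driven selection of the smoothing parameter alpha by
    cluster robustness or embedding entropy, and a synthetic-data
    generator producing modular gene networks with matched cell-type
    expression programs and expression-dependent dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    cluster,
    Rtsne,
    data.table,
    jsonlite,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
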