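Package: nachrevo
Title: Comparative Evolution of Neuronal and Hair-Cell Nicotinic Receptor Subunits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-evolution toolkit contrasting neuronal and hair-cell
    nicotinic acetylcholine receptor (nAChR) subunits. Implements clade-wise
    percent sequence identity and neighbor-joining distance trees, marginal
    maximum-likelihood ancestral sequence reconstruction, a type-II functional
    divergence estimator with per-site posterior probabilities, a single-cell
    expression error model (negative binomial with dropout-Poisson mixture)
    feeding a pentamer-assembly coexpression repertoire classifier, Hill
    dose-response fits, max-normalized PCA of receptor biophysical profiles,
    concatemer trees with 1-SeqID branch lengths, Brownian-motion ancestral
    trait estimation and projection of ancestral receptors into the extant PCA
    space. Includes synthetic-data generators with recorded ground truth for
    every stage, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Biostrings,
    ape,
    phangorn,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
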