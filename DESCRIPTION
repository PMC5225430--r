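Package: gmq
Title: Graph-Based Local Quality Assessment of Protein Structure Models
Version: 0.1.0
Authors@R:
    person("GMQ", "Maintainers", email = "gmq@example.org", role = c("aut", "cre"))
Description: Per-residue (local) quality assessment of protein tertiary
    structure models. A model is represented as a spatial residue graph whose
    nodes are Calpha positions; edges join main-chain neighbours, residues
    within a distance cutoff, and residues sharing a neighbour. A conditional
    random field over the maximal cliques of this graph predicts, for every
    residue, whether its Calpha lies within a chosen error cutoff of the
    native position, combining per-residue structural and alignment features
    with the predicted labels of spatially neighbouring residues. Exact
    inference is performed by sum-product and max-product message passing on
    a junction tree; parameters are trained by stochastic gradient descent.
    Includes secondary-structure-dependent edge weighting, linear and
    logistic-regression baselines, cross-validation and evaluation metrics
    (accuracy, Matthews correlation coefficient), and a synthetic-data module
    generating toy structures, perturbed models and CRF-sampled datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
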