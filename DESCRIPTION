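Package: nichechange
Title: Realized Niche Change Quantification and Ensemble Niche Modelling
    for Invading Species
Version: 0.1.0
Authors@R:
    person("HerpInvasion", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies realized climatic niche changes of invading alien
    species between a native and an invaded range, and assesses the
    consequences for niche-based distribution models.  Implements the
    gridded kernel-density niche comparison of the COUE framework
    (centroid shift, overlap, unfilling, expansion) with Schoener's D and
    permutation tests of niche equivalency and similarity; n-dimensional
    Gaussian kernel hypervolumes compared by Jaccard similarity, distance
    and intersection metrics; and TSS-weighted ensembles of suitability
    models with reciprocal-transfer evaluation and clamping detection.
    Ships a synthetic-data generator with controllable niche dynamics so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
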