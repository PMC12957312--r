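Package: demixgeom
Title: Demixed Subspace Geometry and Manifold Reuse for Multi-Task
    Neural Population Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for population spiking activity recorded
    while subjects learn a series of visuomotor mapping tasks. Provides
    Gaussian-kernel rate smoothing and condition averaging, a demixed
    (dPCA-style) marginalization decomposition into condition-independent,
    stimulus, decision and interaction parts, selection of stimulus- and
    decision-related subspaces, principal angles between subspaces with a
    label-shuffle null, a cross-task manifold-reuse correlation, a small
    temporal-convolution decoder with frozen-parameter cross-task
    evaluation, behavioral learning metrics (trials-to-criterion, reaction
    time, effect sizes, Watson-Williams circular test), a Poisson spiking
    population simulator with known latent geometry, and a plain-text
    session container with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
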