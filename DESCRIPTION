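Package: serialdep
Title: Serial Dependence Analysis of Orientation Working Memory from
    Multichannel Neural Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify serial dependence in orientation working memory
    at the behavioral and neural level. Implements model-free behavioral
    serial-bias indices with stimulus-dependent (cardinal) bias correction,
    cross-validated Mahalanobis-distance tuning-curve decoding of orientation
    from epoched multichannel recordings (sliding-window features, PCA,
    shrinkage-whitened distances, cosine-projected decoding evidence),
    asymmetry-index estimation of neural representational biases sorted by
    inducer stimuli, sensor-space searchlight topographies, cluster-based
    sign-flip permutation inference, and a synthetic-data generator emulating
    retro-cued working memory tasks so that the whole pipeline is testable
    without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'orientation.R'
    'AllClasses.R'
    'AllGenerics.R'
    'epochs-methods.R'
    'io.R'
    'simulate.R'
    'behavior.R'
    'preprocess.R'
    'decoding.R'
    'bias.R'
    'searchlight.R'
    'stats.R'
    'pipeline.R'
    'serialdep-package.R'
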