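Package: conncca
Title: Cross-Modal Prediction of Functional Brain Connectomes with Sparse
    Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical framework for relating whole-brain functional
    connectomes estimated from two modalities, such as band-limited-power
    envelopes of fast electrophysiological recordings and slow hemodynamic
    signals. Provides Ledoit-Wolf shrinkage covariance and normalized
    precision (partial correlation) estimation, sparse canonical correlation
    analysis with permutation-based penalty selection and bidirectional
    connectome prediction, the affine-invariant Riemannian distance on the
    manifold of symmetric positive-definite matrices together with a
    Wishart-based matrix-order calibration, randomized-Lasso stability
    selection of the connections driving the cross-modal relationship, and a
    synthetic-data generator producing coupled paired-modality recordings
    with a known ground truth. Results are returned as tidy tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
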