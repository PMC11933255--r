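Package: memtransfer
Title: Multidimensional Decoding of Episodic Memory Encoding from EEG via
    Transfer Learning with Regularized Common Spatial Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts single-trial episodic memory encoding success (hit vs.
    miss) from multichannel EEG by transferring knowledge from auxiliary
    "source" cognitive tasks (visual perception, sustained attention,
    selective attention) into the memory "target" task.  Implements
    trace-normalized trial covariances, Common Spatial Patterns (CSP) via the
    generalized eigenproblem, Regularized CSP with source-target covariance
    blending and a diagonal channel penalty, Morlet band-power feature
    streams, Fisher-filter plus sequential-forward-selection feature
    selection, SMOTE class balancing, Gaussian naive Bayes scoring within
    nested cross-validation, linear integration of per-source per-window
    evidence scores into a memory prediction, and downstream analyses of
    time-on-task drift and encoding-history effects.  Includes a synthetic
    multi-task EEG generator with controllable class structure, cross-task
    shared discriminative subspaces, slow drift, and latent-state
    autocorrelation so the full pipeline can be exercised without recorded
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
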