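Package: erbforest
Title: Decision Forest Models for Estrogen Receptor Beta Binding Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains and validates Decision Forest classifiers for estrogen
    receptor beta (ERbeta) binding activity from molecular-descriptor tables.
    A Decision Forest combines a small number of deep decision trees built
    sequentially on mutually exclusive descriptor subsets into a consensus
    probability model. The package covers the full modelling protocol:
    logRBA-based binder/non-binder labelling with consensus merging of
    replicate measurements, low-information descriptor filtering, repeated
    unstratified 5-fold cross-validation, label-permutation (y-scrambling)
    testing, prediction-confidence binning, descriptor-frequency importance
    ranking, and application of a trained model to external assay outcomes
    with concordance analysis. A seeded synthetic-data generator reproduces
    the statistical structure of the motivating study (extreme class
    imbalance, planted informative descriptors) so every stage is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
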