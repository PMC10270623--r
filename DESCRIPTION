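Package: patsim
Title: Patient Similarity from Mixed-Type Health Records
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and evaluates lower-dimensional representations of
    mixed-type patient data (numeric, ordinal, binary/categorical features)
    for the purpose of measuring patient similarity. Implements four data
    processing pipelines (multiple correspondence analysis on binned
    features; MCA on categoricals combined with principal component
    analysis on numerics; the same followed by a balancing PCA; and a
    feed-forward autoencoder), the relative-variability (RV) and mean
    relative-variability (MRV) feature-importance metrics, Hopkins
    cluster-tendency and cross-pipeline cluster-congruity evaluation,
    bootstrap pair-stability, clinical vignette export for expert rating,
    and inter-rater agreement statistics (raw agreement, Cohen's kappa with
    large-sample confidence intervals). Includes a synthetic generator for
    COPD-like cohorts with optional planted cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
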