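Package: admespace
Title: ADME Property Space from Consensus QSPR Fingerprints and
    Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Describes drug-like molecules by twenty ternary (-1/0/+1)
    predicted ADME classes produced by consensus QSPR classifiers with an
    uncertain class and an applicability domain, trains a self-organizing
    map (SOM) on these ADME fingerprints, and analyses the resulting 2D
    map: applicability-domain-aware projection of external molecules,
    per-node ADME fingerprints, per-property map layers, and multi-layer
    region colorings for permeability/active-transport, metabolism and
    bioavailability/drug-drug-interaction triage. Includes a synthetic
    data generator (archetype-clustered ternary fingerprints and
    class-conditional descriptor clouds) so the full pipeline runs
    without proprietary descriptor software or private training data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    MASS,
    e1071,
    randomForest,
    ranger,
    rpart,
    xgboost
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
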