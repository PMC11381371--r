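Package: mobstress
Title: Mobility Multigraph Features and Stress Phenotyping from Smartphone
    GPS and Step Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-phenotyping pipeline converting raw smartphone GPS fix
    and step-count streams into mobility features: fixed-area stay-point
    clustering of GPS fixes into location nodes, visit segmentation,
    directed edge-weighted mobility multigraphs with path-weight summaries,
    and daily step quantiles. Scores the DASS stress subscale against
    young-adult population norms, discretizes users into severity groups
    (including a severity-polarized binary scheme), screens features with
    Pearson, Kruskal-Wallis/Dunn and Benjamini-Hochberg statistics, and
    benchmarks six supervised classifier families (elastic-net linear,
    shrinkage discriminant analysis, k-nearest neighbour, CART, random
    forest, feed-forward neural network) with stratified splitting,
    minority oversampling inside cross-validation folds and grid tuning.
    Ships a seeded synthetic cohort generator so the whole pipeline is
    testable without access to real participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lubridate,
    yaml,
    jsonlite,
    glmnet,
    rpart,
    randomForest,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    withr
Config/testthat/edition: 3
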