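Package: m5Cselect
Title: Feature Selection and Positional Profiling of RNA 5-Methylcytosine
    Sites from k-mer Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing RNA 5-methylcytosine (m5C) candidate
    sites from fixed-width sequence windows. Windows of 41 nt centred on a
    candidate cytosine are encoded through a 4-mer embedding table into a
    1020-dimensional feature matrix with full feature-to-position
    provenance; features are ranked by a from-scratch
    minimum-redundancy-maximum-relevance (mRMR) procedure built on
    three-state discretization and plug-in mutual information; ranked
    prefixes are evaluated by incremental feature selection under
    stratified 10-fold cross-validation with decision-tree, k-nearest
    neighbour, random-forest and support-vector-machine classifiers; and
    the selected features of the optimum model are mapped back to window
    positions to produce per-position frequency profiles. A synthetic-data
    module generates labelled windows with plantable downstream motifs and
    deterministic embedding tables so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    class,
    e1071,
    ggplot2,
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
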