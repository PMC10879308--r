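Package: rsmlgcn
Title: Drug Repositioning with Graph Convolutional Matrix Completion and
    Symmetric Metric Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts novel drug-disease associations by combining two
    stages: a graph convolutional encoder with a bilinear decoder that
    completes a sparse binary drug-disease association matrix over a
    heterogeneous drug/disease similarity network, and symmetric
    collaborative metric learning (drug-centric and disease-centric
    triplet hinge losses with adaptive, learned margins) that embeds
    drugs and diseases in a shared Euclidean space where small squared
    distance means likely association.  Includes labeled-matrix I/O,
    seeded synthetic benchmark worlds, cold-start embedding for new
    drugs or diseases, ranking metrics (AUC, AUPR, precision/recall at
    k) and cross-validation, leave-one-entity-out and independent-test
    evaluation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
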