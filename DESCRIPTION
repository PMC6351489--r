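Package: MPrNMF
Title: Multi-View Partially Regularized NMF for lncRNA Function Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology functions of long non-coding RNAs by
    jointly factorizing known gene/lncRNA-ontology associations with a
    nonnegative matrix factorization whose feature matrix is partially
    regularized by several heterogeneous lncRNA-gene association views
    (co-expression and shared-disease). Includes the network-construction
    front end (Pearson co-expression networks, Jaccard disease views,
    bi-colored block matrices), label-propagation and KATZ baselines,
    instability-based rank selection across random restarts, a coupled
    synthetic-data generator with planted functional modules, and a
    threshold-swept micro-averaged Fmax evaluation protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Software, Network, GeneExpression, FunctionalPrediction
RoxygenNote: 7.3.3
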