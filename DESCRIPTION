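Package: ccgnet
Title: Co-Crystal Formation Prediction with Graph Networks and
    Prior-Knowledge Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether two small organic molecules (coformers) will
    form a co-crystal.  Each coformer is represented as a molecular graph
    with a bond-type adjacency tensor plus twelve prior-knowledge molecular
    descriptors used as a global state.  Message passing fuses the two
    representations in stacked co-crystal graph blocks; a multi-head global
    attention readout pools atoms into a pair-level embedding that a dense
    head classifies.  Includes the training, ten-fold cross-validation and
    ensemble-voting protocols, transfer learning for domain-shifted
    molecule families (weight transfer, re-initialization of the last two
    dense layers, full-network finetuning, loss-based member selection), a
    deterministic synthetic coformer-pair generator with a planted
    descriptor rule for end-to-end testing, and a command-line screening
    pipeline with ranked reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for molecular perception and 3D embedding).
Config/testthat/edition: 3
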