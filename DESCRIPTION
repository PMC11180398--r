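Package: ddirisk
Title: Drug-Drug Interaction Risk-Level Prediction with Attention-Enhanced
    Relational Graph Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models drug-drug interaction (DDI) events as a heterogeneous
    graph with one relation per risk level and classifies drug pairs into
    risk classes with a two-layer relational graph convolutional encoder,
    edge-feature propagation, and a multi-head self-attention scoring head.
    Includes Morgan-fingerprint featurization of SMILES with PCA reduction,
    GCN/GAT/GraphSAGE baseline encoders sharing the same classification
    head, cold-start (novel-drug) evaluation splits with five-fold
    cross-validation, micro/macro multi-class metrics, an ablation harness,
    and a seeded synthetic-network generator with planted cluster structure
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
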