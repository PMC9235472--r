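Package: mlpathway
Title: Multi-Label Metabolic Pathway Prediction from Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts which metabolic pathway classes a small-molecule compound
    participates in by jointly learning compound embeddings from molecular
    graphs (a multi-head graph-attention layer followed by a graph-convolution
    layer and a max/mean readout) and pathway embeddings from a directed
    label-dependence graph built from pathway co-occurrence statistics and
    pre-trained word vectors. An adapter network aligns the two embedding
    spaces so that dot products score pathway membership; per-bond attention
    weights provide substructure-level interpretation. Includes the eight
    standard multi-label evaluation metrics, cross-validation orchestration,
    ablation switches, and a synthetic fixture generator with planted label
    co-occurrence and substructure-label associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
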