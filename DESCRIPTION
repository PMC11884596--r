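Package: phosfusion
Title: Multi-Modal Prediction of Functional Phosphorylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts which phosphorylation sites on a protein are
    functional by fusing two views of each site: a residue-level
    structure graph centred on the modified residue (contact edges,
    solvent accessibility, secondary structure, model-confidence and
    network-centrality features) and per-residue protein language-model
    style sequence embeddings, merged through cross-attention and
    self-attention into a classifier. Includes dataset curation rules
    (functional/regulatory labelling, isoform and redundancy filters,
    balanced splits), a transfer-learning extension that classifies
    whether phosphorylation induces or inhibits enzyme activity,
    knowledge distillation into a sequence-only multilayer perceptron,
    an evaluation harness (AUROC, AUPR, accuracy, precision, recall,
    F1, MCC, confidence-stratified recall), descriptive site statistics,
    and a synthetic-data generator so the whole pipeline trains and
    tests on one CPU without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
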