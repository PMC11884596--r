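# phosfusion

Most phosphorylation sites detected by mass spectrometry have no known
function. `phosfusion` is an R package for predicting which
serine/threonine/tyrosine phosphosites are *functional* — annotated
with a downstream regulatory role or disease association — and, for
sites on enzymes, whether phosphorylation *induces* or *inhibits*
catalytic activity. It is aimed at computational biologists who work
with AlphaFold-style structure models and phosphoproteomics site
tables.

## The model

Each candidate site is scored by fusing two views:

* **Structure view.** A residue graph centred on the site: the node
  set is the site plus all residues whose Cα lies within 8 Å, plus the
  site's 3 nearest residues; edges combine distance (< 8 Å), site-kNN
  and peptide-bond rules with at most one edge per pair. Every node
  carries a 35-dimensional feature vector — amino-acid one-hot (20),
  relative solvent accessibility (1), pLDDT (1), the Cα→sidechain
  centre vector (3), 8-state secondary structure one-hot (8), contact
  degree (1) and eigenvector centrality (1) — and is encoded by a
  two-layer graph convolutional network
  H^(l+1) = σ(D̃^(-1/2) Ã D̃^(-1/2) H^(l) W^(l)).
* **Sequence view.** Per-residue embeddings from a pluggable
  language-model backend (a deterministic mock backend ships with the
  package, so everything runs on one CPU with no downloads), pooled
  into a global token plus the site token, projected to the fusion
  width C.

The views are merged by single-head scaled dot-product attention,

  attention(q, k, v) = softmax(q kᵀ / √(C/d)) v,

with queries from the sequence tokens and keys/values from the graph
encoder (cross-attention), followed by self-attention over the fused
tokens and a three-hidden-layer classifier (256/256/512, dropout 0.3)
ending in a sigmoid. Scores above 0.5 are called functional. Training
minimises binary cross-entropy with AdamW under five-fold
cross-validation with early stopping. The enzyme regulatory-type model
(`finetune()`) warm-starts from the functional-site model —
transferring either all parameters or all non-classifier layers — or
trains multi-task with the summed BCE loss; `distill_student()`
compresses the fused model into a sequence-only MLP via soft-target
distillation.

The package also implements the surrounding study: curation rules
(functional/regulatory labelling, isoform removal, greedy 0.8-identity
redundancy reduction, 1:1 undersampling with three independent
negative sets, 4:1 train/test split), the evaluation harness (AUROC,
AUPR, accuracy, precision, recall, F1, MCC, pLDDT-stratified recall,
score–pLDDT Spearman correlation), descriptive site statistics
(Welch t-tests, secondary-structure composition) and a synthetic-data
generator that plants a known logistic rule over coil location,
eigenvector centrality and a +1-proline motif, so every stage is
testable against ground truth.

## Worked example

```r
library(phosfusion)

dat    <- generate_synthetic_dataset(synth_config(n_proteins = 60, seed = 7))
ds     <- build_model_dataset(dat$proteins, dat$sites, graph_config(),
                              embedder_config(mock_dim = 64, seed = 7))
splits <- make_splits(dat$sites, curation_config(n_negative_sets = 1, seed = 7))
cfg    <- fusion_config(embed_dim = 48, dropout = 0.1, seed = 7)
tcfg   <- train_config(learning_rate = 2e-3, epochs = 20, patience = 5, seed = 7)

cv <- train_cv(ds, splits, cfg, tcfg, folds = 1)
cv$fold_metrics[["1"]]
#> AUROC 0.894  AUPR 0.875  Acc 0.839  Prec 0.817  Rec 0.875  F1 0.845  MCC 0.680

tab <- build_feature_table(dat$proteins, dat$sites)
round(class_composition(tab, "ss3"), 3)
#>                f
#> grp              coil helix strand
#>   functional    0.427 0.214  0.359
#>   nonfunctional 0.050 0.893  0.057
compare_groups(tab, "centrality")
#> centrality: functional higher (t = 5.40, p = 1.1e-07)
```

The 60-protein corpus plants 562 sites (281 functional). A single
cross-validation fold already recovers the planted signal (held-out
AUROC 0.894): functional sites sit preferentially outside helices and
at higher-centrality residues, which is exactly the structure the
generator builds in and the structure branch is designed to read out.

A thin command-line wrapper over the same functions is installed at
`inst/cli/phosfusion.R`:

```sh
Rscript inst/cli/phosfusion.R simulate --n-proteins 200 --seed 1 --out data/
Rscript inst/cli/phosfusion.R train --data data/ --seed 1 --out run/
Rscript inst/cli/phosfusion.R predict --checkpoint run/checkpoint.json \
        --data data/ --out run/
```

Every run writes a `manifest.json` with the configuration, seed and
input hashes.

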