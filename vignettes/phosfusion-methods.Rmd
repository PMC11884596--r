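---
title: "phosfusion: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phosfusion: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `phosfusion`: the
model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open and a
decision had to be made.

## The prediction problem

A phosphorylation site is a serine, threonine or tyrosine residue that
can carry a phosphate group. Only a minority of detected sites have a
known downstream effect; the package's primary task is to classify a
site as *functional* (annotated with a regulatory role or disease
association) versus *non-functional* (no such annotation). A second,
smaller task classifies sites on enzymes by *regulatory type*: whether
phosphorylation induces or inhibits catalytic activity (positive class
= induced; a score above 0.5 means predicted enhancement).

The modelling assumption throughout is that functionality is encoded
jointly in (a) the local three-dimensional neighbourhood of the site —
flexibility, exposure, packing, network position — and (b) the
sequence context as summarised by per-residue embeddings. Neither view
suffices alone; the model is built to fuse them.

## Site-centred structure graphs

For a site at residue *s*, the node set is `{s}`, every residue whose
Cα lies within `radius` (default 8 Å, a standard residue-contact
cutoff) of the Cα of *s*, and the `knn_k = 3` nearest residues of *s*
(guaranteeing local context even for isolated sites). Edges combine
three rules — any node pair closer than 8 Å, site-to-kNN, and peptide
bonds between sequence-adjacent nodes — collapsed to at most one edge
per pair. Distances are Cα–Cα, since nodes are defined as Cα atoms.
When several rules coincide the edge keeps the first matching tag in
the order distance, knn, peptide; the tag is bookkeeping only and does
not affect the model.

Each node carries 35 features. The layout (amino-acid one-hot 20, RSA
1, pLDDT 1, sidechain vector 3, secondary-structure one-hot 8, degree
1, eigenvector centrality 1) is the unique integer split of the seven
residue properties consistent with a 35-dimensional total, given
one-hot amino acids, an 8-state secondary-structure alphabet, scalar
RSA/pLDDT/degree/centrality and a 3-vector sidechain direction.
Degree and centrality are computed by default on the *whole-protein*
contact graph (8 Å rule over all residues) rather than on the
extracted subgraph: the descriptive statistics of functional sites use
these quantities before any subgraph exists, and a site-local subgraph
has near-constant degree by construction. `graph_config(centrality_scope
= "subgraph")` restores the subgraph variant for ablations.

Three standard structure annotations are computed in-package:

* **Secondary structure** comes from a P-SEA-style geometric assigner
  on Cα distances d(i, i+2), d(i, i+3), d(i, i+4) compared with their
  ideal helix values (5.43 / 5.05 / 6.20 Å, ±0.55); extended stretches
  (d(i,i+2) > 6.3 Å and d(i,i+3) > 9.0 Å) are strands; everything else
  is coil. It emits only H/E/C within the 8-letter alphabet; chains
  shorter than 5 residues are all coil. An external DSSP can replace
  it where the full 8 states or hydrogen-bond accuracy matter.
* **RSA** is Shrake–Rupley accessible surface over a reduced sphere
  model (a 2.0 Å backbone sphere at each Cα plus a residue-specific
  sidechain sphere at the sidechain centre; probe 1.4 Å; 92
  deterministic Fibonacci sphere points), normalised by the
  residue's theoretical maximum ASA (Tien et al. 2013 values) and
  clipped to [0, 1]. This is a coarse but monotone exposure measure;
  tests verify it against a 960-point quadrature.
* **Eigenvector centrality** is the principal eigenvector of the
  adjacency matrix, computed per connected component by power
  iteration from the uniform vector (tolerance 1e-8, at most 1000
  iterations), entries nonnegative, each component L2-normalised. The
  iteration runs on A + I: bipartite components (stars, paths) have a
  symmetric spectrum and the unshifted iteration oscillates; the shift
  leaves the eigenvector unchanged. A single-node component scores 1,
  its trivial normalised eigenvector.

## Sequence embeddings

The embedder is pluggable. The shipped `mock` backend produces, for
residue *i*, the unit-normalised sum of a letter vector and a
half-weight vector keyed by the residue's 16-residue position bucket,
all deterministic functions of `(seed, letter, bucket)`. Identical
residues in nearby positions embed similarly; different letters embed
near-orthogonally; identical inputs give bitwise-identical output.
The `plm` backend is an explicit extension point for a real protein
language model (native width e.g. 2560) and raises an error rather
than silently falling back. Sequences longer than the backend context
(`crop_window`, default 1022) are centre-cropped around the site.

The model's query is the two-token sequence `[global; site]`: the
mean-pooled embedding and the site residue's embedding, linearly
projected to the fusion width. Mean pooling is the standard choice
for the model family; the exact query composition was an open design
point, so a windowed variant (`query_window = w` gives the global
token plus the 2w+1 rows around the site, zero-padded at chain ends)
is also available and is what the distillation experiment uses.

## Fusion model

With fusion width C (default 256; desk-scale experiments use 48) and a
single attention head d = 1:

* the graph branch applies `gcn_layers` (default 2) rounds of
  symmetrically normalised aggregation (35 → C on entry,
  rectified-linear between layers, linear output), exposing per-node
  vectors, their mean pool, and the centre node's raw features behind
  a linear projection;
* cross-attention uses the projected query tokens as q and the graph
  outputs as k and v, `softmax(q kᵀ / √(C/d)) v`, followed by an
  output projection. The typeset scaling was ambiguous between
  dividing by C/d and √(C/d); the standard scaled dot-product √(C/d)
  is the default and `attention_scale = "linear"` exposes the
  alternative;
* the fused token set entering self-attention is the cross-attended
  query tokens plus, by default, the mean-pooled graph token
  (`pool_token`) and the projected centre-node token (`center_token`).
  Whether the pooling output participates in fusion was unstated in
  the source architecture; including it — and a direct readout of the
  site's own feature vector — is this package's resolution. The
  motivation is measurable on synthetic data: the planted signal lives
  on the centre residue, and both mean pooling and neighbourhood
  aggregation dilute it by roughly the subgraph size, capping what a
  pool-only readout can linearly recover. A site-centred readout is
  the natural fix for a site-centred subgraph and both tokens are
  togglable for ablation;
* self-attention applies the same formula with q = k = v over the
  fused tokens; the classifier concatenates the tokens and applies
  widths 256/256/512 with rectified-linear activations, dropout
  (default 0.3) on hidden layers in training mode, and a sigmoid.
  Nonlinearities and normalisation were unstated; plain ReLU without
  layer normalisation is used throughout.

Training minimises clamped binary cross-entropy (ε = 1e-7) with AdamW
(decoupled weight decay 0.01 on weight matrices, not biases), batch
128. Reference-scale defaults are learning rate 1e-4 and 50 epochs;
the desk-scale experiments use 2e-3 and at most 40 epochs because the
48-dimensional model on ~1500 training sites converges in 10–20
epochs. Early stopping watches validation AUROC with patience 5 and
always returns the best epoch's parameters. Gradients are exact
(hand-written backward pass, verified against finite differences to
1e-4 relative in the test suite), and a fixed seed reproduces the loss
trajectory bitwise. Node features are z-scored at the dataset level
(one-hot blocks excluded) so that degree (~0–15) does not dominate
dot products; graph objects keep raw features, and the stored scaling
is reapplied to prediction-time datasets.

Ablation modes are first-class configuration: `no_gcn` (queries pass
straight to self-attention), `no_esm` (pooled graph vector classifies),
`no_cross` (branch outputs concatenated as tokens without
cross-attention), `no_self`.

## Curation rules

Functional labels: a site is positive when its annotation set contains
a regulatory-function or disease-association tag, otherwise negative.
Regulatory types: sites annotated "enzymatic activity, inhibited" are
inhibited even when an induced tag is also present (inhibited wins, so
conflicting labels cannot leak into the induced class); sites with
neither tag are dropped. Protein filters run in order — isoform
accessions (hyphen-numbered suffix), proteins without structures,
sites whose residue letter mismatches the sequence — and are
idempotent.

Redundancy reduction follows cd-hit's semantics at 0.8 identity
without re-implementing its heuristics: greedy longest-first
clustering with a k-mer-anchored (k = 5) ungapped identity, matched
positions over the shorter length. Tests verify the resulting
partition against a Needleman–Wunsch identity oracle; an external
cd-hit binary can be plugged in.

Splitting undersamples negatives globally at 1:1 (configurable, e.g.
1:2 or 1:3), builds three independent negative sets, splits 4:1
train/test stratified by class and partitions training sites into five
stratified folds, all reproducible from one seed. Whether the original
protocol grouped the 4:1 split by protein is unstated; plain
site-level splitting is the default and `group_by_protein = TRUE`
provides the leakage-aware variant. How the three negative sets fed
the final reported numbers is also unstated, so per-set, per-fold and
mean metrics are always available.

## Evaluation

Accuracy, precision, recall, F1 and MCC come from confusion counts at
the strictly-greater-than-0.5 threshold (the measure-zero tie goes to
the negative/inhibited class). AUROC is the rank (Mann–Whitney)
statistic with average-rank ties; AUPR is interpolation-free
summation over threshold blocks. Conventions for degenerate cases:
MCC with a zero denominator is 0; precision with no predicted
positives is 0; single-class rank metrics are reported missing with a
warning. pLDDT-stratified recall uses the bins below 30, 30–50,
50–70, 70–90 and 90+, half-open `[lower, upper)` with the top bin
closed at 100. The Spearman score–pLDDT correlation uses average
ranks and reports missing for constant input.

## The synthetic generator

The generator exists so that every stage is trainable and testable on
one CPU with known ground truth. It emulates the statistical structure
the model assumes: chains of 60–180 residues alternate ideal α-helix
segments (rise 1.5 Å, radius 2.3 Å, 100°/residue; pLDDT ~ U(70, 95))
and self-avoiding random-coil segments (3.8 Å steps; pLDDT
~ U(30, 60)); non-site residues draw from helix-former or coil-former
letter frequencies so local sequence carries structural context the
way real sequences do; sidechain pseudo-atoms sit at a unit offset in
a random direction (absent for glycine). Candidate sites (~0.085 per
residue, S/T/Y, two residues apart at minimum) receive a +1 proline
with probability 0.35.

Labels are drawn from the planted logistic rule

  P(functional) = σ(4.0·coil + 1.0·z(centrality) + 1.5·motif − 2.5),

with z the dataset-standardised whole-protein eigenvector centrality.
The weights were fixed once, at design time, by three conditions: a
logistic regression on the true generative features must recover each
weight within ±20% and score AUROC ≥ 0.9 at the default corpus size
(the planted signal is strong enough to be learnable); the classes
are near-balanced after the bias; and positives show the qualitative
signatures the real corpus shows — enriched on coils, at
low-confidence residues, and at higher-centrality residues. The
regulatory-type truth uses a partially overlapping rule
(2.5·coil + 1.0·z − 1.5·motif − 0.8), sharing the structural weights
so that transfer from the functional-site model genuinely helps while
the motif term flips sign.

What the generator does **not** emulate: real secondary-structure
diversity (no sheets pairing through space), rotamer-level sidechains,
kinase-specific sequence motifs, evolutionary conservation, domain
architecture, or embeddings that encode structure the way a real
protein language model does. Passing the synthetic benchmark
therefore demonstrates that the machinery is correct and that the
architecture can recover a planted structure-borne signal at desk
scale — not that the packaged weights predict real phosphoproteomes;
training on a licensed site corpus with AlphaFold structures and a
real embedder is required for that.

## Desk-scale experiment sizes

`run_synthetic_study()` (also behind `scripts/acceptance.R`) uses 200
proteins (~1900 sites), a 64-dimensional mock embedder, fusion width
48, one negative set, five-fold cross-validation, and single-fold
controls (label-shuffled and no-graph). These sizes were chosen so the
study completes in minutes on one CPU while leaving clear daylight
between the full model, the logistic oracle above it, and the
controls below it. The distillation experiment uses the windowed
query (window 3) for teacher and student — the desk-scale analogue of
distilling from rich language-model context — and a transfer set of
twice as many unlabeled proteins scored by the teacher, with the
student selected by held-back correlation.

## Known limitations

* **Distillation fidelity is bounded by the mock embedder.** The
  teacher's probabilities depend on continuous structural features
  (pLDDT values, centrality, exposure). A real language-model
  embedding encodes much of that implicitly; the mock embedding
  carries only residue identity and a coarse position bucket, so a
  sequence-only student can at best reconstruct what letters reveal.
  An oracle student given the true window coil states, motif and site
  letter still falls short of the fidelity a real-embedding student
  reaches, and the measured student–teacher correlation in the
  acceptance run sits well below it. The distillation machinery is
  exercised and correct; high fidelity requires structure-aware
  embeddings.
* The geometric secondary-structure assigner misclassifies extended
  coil as strand more often than DSSP would; the statistics module
  reports both the 8-state letter and the collapsed class, and an
  external DSSP can be substituted.
* The sphere-model RSA is monotone but not atom-accurate.
* The greedy clustering reproduces cd-hit's threshold semantics, not
  its exact clusters, on borderline pairs.
* Multi-head attention is configurable but untested territory; the
  reference architecture uses one head.
* Non-standard residues map to X (all-zero one-hot with a warning)
  and are excluded as site candidates; multi-chain structures use the
  first chain with a warning; B-factors of experimental structures
  are treated as a pLDDT stand-in and should be interpreted as such.
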