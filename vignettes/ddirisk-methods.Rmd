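---
title: "Methods: relational graph convolutions with attention for DDI risk levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relational graph convolutions with attention for DDI risk levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

Given a set of drugs with known structures (SMILES) and a partial record
of pairwise interaction events graded into `R` risk classes, predict the
class of an unrecorded pair. `ddirisk` treats the record as a
heterogeneous graph: one node per drug, one undirected edge relation per
risk class, stored as double-entry directed arcs because message passing
iterates arcs. The symmetric risk-rating matrix `Y` (class of each
recorded pair, sentinel elsewhere) is an equivalent view provided by
`risk_matrix()`. In the four-level regime, "Unknown" is an ordinary class
— an annotated-but-unexplained interaction, not an absent record — and
non-recorded pairs are simply absent from the graph. The ordinal coding
Unknown 0 < Minor 1 < Moderate 2 < Major 3 puts higher risk at higher
codes; it is a documented convention, configurable through the label map
of `read_edge_list()`.

## Featurization

Node attributes are Morgan (extended-connectivity) fingerprints of the
SMILES, radius 2 over 2048 bits by default — the field-standard
ECFP4-equivalent. Fingerprinting delegates to OpenBabel through
ChemmineOB; radius `r` maps to the ECFP`2r` fingerprint type, and the
4096-bit backend output is OR-folded to the requested width. Because
OpenBabel silently repairs some malformed SMILES, validity checking
combines a bracket/ring-closure balance pre-check with canonicalization.
Bit vectors are converted to 0/1 reals and reduced by PCA: the projection
is the top-`k` eigenvector matrix of the `1/m`-scaled covariance of the
mean-centered data (computed by SVD), eigenvector signs fixed by making
each column's largest-magnitude entry positive so results are identical
across linear-algebra backends. PCA is fit on all drugs by default —
features derive from chemistry only, so no label information can leak —
with `fit_rows` available to restrict fitting to training drugs under a
stricter protocol. `pca_k_sweep()` reports the cumulative
explained-variance curve used to choose `k`; the package default is
`k = 300` for real-scale fingerprint data, while the bundled experiments
use `k = 64`, past the variance plateau of the synthetic chemistry. An
edge's attribute is the concatenation of its endpoint features in arc
order.

## Encoder

Two relational graph convolution layers update node states as

$$x_i^{(l+1)} = \sigma\Big( W_0^{(l)} x_i^{(l)} + \sum_{r=1}^{R}
\sum_{j \in N_i^r} \tfrac{1}{c_{ij}} W_r^{(l)}\big(x_j^{(l)} + P^{(l)} w_{ij}\big) \Big)$$

with ReLU between layers. Design choices that the formulation leaves
open, fixed here and exposed as configuration:

* **Edge fusion.** The propagated quantity adds the neighbor state to a
  linear projection of the arc attribute into the layer's input space.
  Because arc attributes are endpoint concatenations, the projection
  factorizes into two node-level matrices, which the implementation
  exploits; the generic per-arc form is kept in `rgcn_layer_forward()`
  and `edge_message()`.
* **Normalization.** `c_ij = |N_i^r|`, the per-relation in-degree (the
  standard mean normalizer); a `"none"` option disables it.
* **Self-connection.** A separate `W_0`, added before the activation.
* **Weight decomposition.** Basis mode by default with `B = R` bases
  (`W_r = Σ_b a_rb V_b`); block-diagonal and unconstrained modes are
  implemented and tested, including the `B = d` diagonal limit.

## Edge scoring head

For each queried pair the head fuses the two endpoint states (by sum, so
the undirected pair has one latent) with the edge attribute through a
ReLU layer, then refines the batch's latent sequence with multi-head
self-attention (`softmax(QKᵀ/√d_k)` per head, 2 heads over width 64 by
default), a residual connection, and layer normalization
(`(x − E[x])/√(Var[x]+ε) ⊙ γ + β`, post-norm placement), and finally a
linear map to `R` class logits. Two deliberate deviations from the
conventional transformer block, both switchable:

* **Value path.** By default the attention weights multiply the fused
  input latents themselves rather than a learned value projection,
  mirroring a formulation in which attention reweights the summed
  endpoint features; `learned_value = TRUE` restores the standard form.
* **Blocked attention.** Self-attention runs within blocks of at most
  `attn_block = 256` edges — reshuffled every training epoch, input-order
  at inference. This bounds the quadratic cost and, empirically, the
  varying attended context regularizes the head: with whole-batch
  attention the `Wq/Wk` projections can memorize the training batch's
  geometry and generalize poorly.

Softmaxes subtract the row maximum before exponentiation, and attention
mass below `1e-20` of the row maximum is flushed to exact zero — it is
negligible against the softmax sum and keeps denormalized numbers out of
the matrix products (a large slowdown on most FPUs).

## Training

Full-batch AdamW (lr `1e-3`, decoupled weight decay `1e-2`, up to 300
epochs by default; biases and layer-norm parameters are exempt from
decay) on the cross-entropy `J = −(1/m) Σ log ŷ_{i,y_i}`, with
probabilities at the true label clamped at `1e-12` in the standalone loss
function. A stratified 10% of the training edges is held out for model
selection: parameters with the best held-out accuracy are returned (ties
broken by loss), and training stops once neither held-out loss nor
accuracy has improved for 50 epochs (loss improvements smaller than
`1e-4` do not reset the clock). Held-out edges are removed from the
message-passing graph, not just the loss — a typed edge's presence in the
graph would reveal its own label. Selection on accuracy rather than loss
is deliberate: the stochastic attention blocks add calibration noise to
the loss that the argmax decision ignores. The loss clock matters on
partially random labels, where held-out accuracy can sit at the majority
rate for many epochs while genuine structure is still being absorbed.
Validation is skipped for tiny edge sets (held-out < 20 edges), where the
split would be meaningless. All randomness — initialization, the
validation split, block shuffling — derives from the training seed; two
runs with the same seed produce bitwise-identical loss histories.

Backpropagation is hand-written in base R with BLAS matrix ops (no
automatic-differentiation framework is used); every layer's gradient is
verified against central finite differences in the test suite, for every
encoder and ablation variant.

## Baselines

GCN (`σ(D̃^{-1/2}ÃD̃^{-1/2}HW)` with self-loops), GAT (LeakyReLU-scored
softmax attention over the in-neighborhood, self-loops added so isolated
nodes are well-defined), and GraphSAGE (mean aggregator over self and
neighbors, or max-pooling over FC-projected neighbors concatenated with
the self state) — each two layers, collapsing the typed relations into
one untyped adjacency, since these are single-relation formulations.
Relation information reaches them only through the shared edge-scoring
head (without the attention block, which is specific to the relational
model). Layer counts and widths mirror the relational encoder for
fairness; GraphSAGE is trained supervised only, and the LSTM aggregator
is out of scope.

## Evaluation protocol

Task 1 five-fold cross-validation stratifies edge folds by class —
imbalance at a few thousand edges otherwise leaves folds without minority
classes. Cold-start Tasks 2 and 3 instead repeat the novel-drug protocol
five times: sample `⌈0.2·|V|⌉` drugs as novel (a documented default; the
fraction is a knob), train on confirmed-pair edges only, and test on
confirmed–novel or novel–novel pairs. A leak-freedom invariant — no
novel-endpoint edge in any training or message-passing set — is asserted
over 100 random seeds in the tests.

Metrics follow the convention of micro-averaged AUPR and AUC over the
flattened one-vs-rest label indicator matrix, with accuracy (pooled
argmax), precision, recall and F1 macro-averaged over classes. Recall is
additionally reported micro-pooled, where it coincides with accuracy for
single-label argmax predictions — both averaging modes are computed
because conventions differ. Macro averages skip, with a warning, classes
absent from the truth; a never-predicted class contributes precision 0;
single-class truth makes the rank metrics undefined and they are reported
as `NA`, never 0. AUC is the midrank Mann–Whitney statistic; AUPR is
step-wise average precision.

## The synthetic benchmark

`generate_network()` emulates the study conditions without external data:
drugs receive latent clusters (8 by default); each drug's SMILES is a
valid base molecule from a fixed bank of ~50 small molecules, decorated
with three copies of its cluster's substituent motif, so fingerprints
separate clusters sharply; a seeded sample of unordered pairs becomes the
event list, labeled from a cluster-pair table with probability equal to
`feature_label_coupling` and from the class-proportion prior otherwise.
The table is built greedily so that pair-frequency-weighted class shares
respect the requested proportions and every class is reachable. The
`ddinter4` preset mirrors a curated 4-level severity resource's shares
(≈ 21.3 / 4.9 / 58.6 / 15.2% for unknown/minor/moderate/major);
`drugbank65` gives a 65-class long-tailed regime. Default size is 300
drugs at edge density 0.1 — the same order of connectivity as the curated
network the preset mirrors (which has roughly one recorded event per six
drug pairs) at a desk-scale node count. The bundled experiments and the
acceptance script run at these sizes with `k = 64`, hidden width 64, and
training capped at 100 epochs, past the point where early stopping
typically fires.

At coupling 1 the Bayes-optimal classifier on endpoint clusters is
perfect, so Task-1 accuracy near 1 is the designed outcome, and the
fingerprint-free ablation bounds what topology alone achieves; at
coupling 0 any feature-based classifier can do no better in expectation
than the majority share, which pins the noise floor the early-stopped
model should sit at. What passing these checks does **not** show: real
DDI labels are not a deterministic function of chemical similarity
clusters, real fingerprint space is far noisier, and mechanism
annotations, dosing and directionality are absent here — absolute
accuracies on this benchmark say nothing about accuracy on curated data,
only that the machinery (featurization, propagation, attention, splits,
metrics) is implemented correctly and recovers structure that is present
by construction.

## Numerical and degenerate-input choices

* Glorot-uniform initialization throughout, seeded; the coefficient
  matrix of the basis decomposition is Gaussian with sd `1/√B`.
* Nodes without neighbors in a relation contribute only the
  self-connection term; empty relations are skipped.
* Duplicate unordered pairs, self-pairs, unknown labels and unknown drug
  ids are hard errors at load time — label conflicts indicate corrupt
  input, and keep-first behavior would hide them.
* Unparseable SMILES are dropped with a warning and counted in a drop
  report at load; they are hard errors at fingerprint time.
* Zero-variance PCA input is an error; `k` is capped at `min(m, n)`.
* Attention width must divide the head count; block-diagonal
  decomposition requires the block count to divide both layer widths.

## Known limitations

* Full-graph message passing bounds the node count at desk scale; no
  neighbor sampling or GPU path is provided.
* The attention head scores edges in batch context, so logits depend
  (mildly) on the composition of the scored batch; blocked inference in
  input order makes this deterministic.
* One label per unordered pair: multi-mechanism annotations must be
  reduced to a single class upstream.
* The 65-class preset exercises shapes and metrics, but 300-drug
  networks leave tail classes with very few events per fold, so macro
  metrics there are noisy by construction.
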