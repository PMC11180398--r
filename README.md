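# ddirisk

Multi-class risk-level prediction for drug–drug interactions (DDIs) with a
relational graph convolutional encoder and an attention-based edge-scoring
head, in pure R.

Co-prescribing two drugs can trigger interactions whose clinical severity
ranges from negligible to life-threatening. Curated DDI resources grade
each known interacting pair with an ordinal risk level (Major / Moderate /
Minor / Unknown) or with one of many mechanistic event types, but the vast
majority of drug pairs — and every pair involving a newly developed drug —
is unannotated. `ddirisk` is for computational pharmacologists and method
developers who want to predict the risk class of an unseen drug pair from
two inputs only: the molecular structures (SMILES) of the drugs and the
topology of the known interaction network.

## The model

The known events form a heterogeneous graph `G = (V, E)`: drugs are nodes
and each risk class `r ∈ {1..R}` is its own edge relation. Each drug's
SMILES is encoded as a Morgan (extended-connectivity) fingerprint, reduced
by PCA (`Y = X·P`, with `P` the top-`k` eigenvectors of the `1/m`-scaled
covariance); an edge's attribute is the concatenation of its endpoint
features. Node states then pass through two relational graph convolution
layers with per-relation weights and edge-feature propagation,

    x_i^(l+1) = σ( W_0 x_i^(l) + Σ_r Σ_{j∈N_i^r} (1/c_ij) W_r^(l) (x_j^(l) + P w_ij) ),

with `c_ij = |N_i^r|` and the relation weights factorized by basis
decomposition `W_r = Σ_b a_rb V_b` (block-diagonal and unconstrained modes
are also provided). For each queried pair the model recomputes an edge
latent from its two endpoint states and the edge attribute, refines the
batch of edge latents with multi-head self-attention
(`softmax(QKᵀ/√d_k)`, residual + layer norm), and scores `R` classes with
cross-entropy training under AdamW. GCN, GAT and GraphSAGE baselines share
the same edge-scoring head. Cold-start evaluation splits drugs into
confirmed and novel sets, trains only on confirmed–confirmed (Task 1)
edges, and tests on confirmed–novel (Task 2) and novel–novel (Task 3)
pairs — novel-endpoint edges never reach the training graph.

A seeded synthetic-network generator plants cluster structure in the
chemistry (cluster-specific substructure motifs on valid SMILES) and makes
edge labels a cluster-pair function with tunable feature–label coupling,
so recoverability is known by construction and the whole pipeline is
testable offline.

## Worked example

```r
library(ddirisk)

net <- generate_network(imbalance_preset("ddinter4", seed = 7))
net
#> <synthetic_network> 300 drugs, 4485 events, 4 classes, coupling 1.00, 8 clusters

cv <- five_fold_cv(net$events, net$drugs,
                   train_config(epochs = 100, seed = 11, feature_dim = 64,
                                n_relations = 4),
                   task = 1)
cv
#> <cv_result> task 1, 5 folds
#>         metric   mean        sd
#> 1          acc 0.9891 0.0055535
#> 2    precision 0.9916 0.0077886
#> 3       recall 0.9776 0.0133311
#> 4 recall_micro 0.9891 0.0055535
#> 5     f1_macro 0.9843 0.0105318
#> 6    auc_micro 0.9981 0.0009725
#> 7   aupr_micro 0.9952 0.0025147
```

An accuracy of 0.989 against a 0.591 majority-class share says the
encoder recovered the planted cluster-pair labeling from chemistry plus
topology; the same call with `ablation = "no_fp"` (topology only) loses
several points, and `task = 2` or `3` quantifies the cold-start penalty
for drugs never seen in training.

Files on disk work the same way: `read_smiles_table()` +
`read_edge_list()` load any two-column drug table and typed edge list, and
`inst/scripts/ddirisk-cli.R` exposes `simulate / featurize / split /
train / evaluate / ablate` subcommands.

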