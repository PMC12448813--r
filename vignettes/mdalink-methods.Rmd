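---
title: "Predicting microbe-drug associations with knowledge-graph propagation and contrastive learning"
author: "mdalink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbe-drug associations with knowledge-graph propagation and contrastive learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdalink)
```

## The problem

Microbes modulate drug metabolism, efficacy and resistance, and screening
every microbe-drug pair in the laboratory is infeasible. Given a sparse
binary interaction matrix $A \in \{0,1\}^{M \times N}$ (rows: microbial
taxa, columns: drug compounds, $A_{md} = 1$ for a verified interaction) and
a biomedical knowledge graph $G = \{(h, r, t)\}$ over entities that include
the microbes and drugs themselves plus attribute entities (pathways,
metabolites, resistance genes, ...), the task is to score unobserved pairs
so that true latent associations rank above non-interacting pairs.

`mdalink` treats this as bipartite link prediction enriched by the KG.
Only positive pairs are observed; unobserved pairs are treated as unknowns
from which negatives are sampled, and evaluation uses balanced held-out
sets, so all results are of the positive-unlabelled kind.

## Model

### Layered graph construction

For every anchor node $u$ (each microbe and each drug) two layered
neighbourhoods are built:

* **Local graph.** The layer-0 entity set contains the aligned KG entities
  of $u$'s direct interaction partners, plus $u$'s own aligned entity.
  Including the anchor itself is a deliberate choice: the equations
  defining the seed set are ambiguous on this point, and including it
  guarantees that isolated nodes still carry a layer-0 representation
  instead of an all-zero embedding stack.
* **Non-local graph.** The seeds are the aligned entities of $u$'s
  *high-order* partners: for a microbe $m$, the drugs interacted with by
  microbes that share at least one drug with $m$, minus $m$'s own drugs
  (and symmetrically for drugs, a case the source description leaves
  implicit). Both the anchor and its first-order partners are excluded so
  this graph carries strictly higher-order collaborative-filtering signal.

Each seed set is expanded for $L$ layers: layer $l$ collects every triple
whose head lies in the layer-$(l-1)$ entity set, and the layer-$l$ entity
set is the set of retained tails. Propagation follows directed
head-to-tail edges; for graphs where inverse traversal matters,
`read_triples(undirected = TRUE)` materializes inverse relations at load
time. Because nothing bounds the triple count per layer on dense graphs,
each layer is uniformly subsampled without replacement to a per-anchor
`layer_budget` (default 64); an exhausted frontier simply leaves deeper
layers empty.

### Embeddings and attention encoding

Entity and relation vectors (dimension $d$, default 64) are pre-trained
with the translational TransE objective $h + r \approx t$, scored by
$f(h,r,t) = \lVert h + r - t\rVert$ and optimized with the margin hinge
$\max(0, \gamma + f(\text{pos}) - f(\text{neg}))$ over uniformly corrupted
triples. The printed form of this hinge in the source description has its
arguments in the reverse order, which would reward implausible triples;
the canonical orientation is implemented. TransE output *initializes* the
trainable tables, it is not frozen — its role is to start optimization
from a geometry that already respects the KG. Canonical TransE settings
(margin 1, L2 norm, one negative per positive, per-epoch entity
renormalization) are used since none are prescribed.

Each layer's triple set is encoded into one vector by multi-head scaled
dot-product attention. Per triple $i$, the query is a learned projection
of $[h_i \Vert r_i]$ and the key and value are projections of $t_i$. As
printed, the query ($2d$) and key ($d$) dimensions cannot be dotted, so
per-head projection matrices to $d_h = d/H$ (default $H = 4$ heads) are
introduced — the standard multi-head resolution — initialized from a
seeded uniform Glorot-style distribution and trained jointly with the rest
of the model. Attention with per-triple queries yields one output per
query while the model needs one vector per layer; the attended values are
therefore mean-pooled over the query axis per head before the heads are
concatenated and projected back to $d$. This is the simplest
set-to-vector reduction consistent with aggregating tail information, and
it keeps the encoder permutation-invariant over the layer's triples.
Empty layers encode to the zero vector so every anchor contributes a
shape-stable stack of $L + 1$ vectors per context. The attention-free
ablation (`no_att`) replaces the encoder by the unweighted mean of tail
embeddings.

### Contrastive regularization

Two InfoNCE terms regularize the layer embeddings, both using the raw dot
product as similarity (the defining equations carry no normalization;
cosine is available behind a flag) at temperature $\tau = 0.1$:

* **Intra-graph.** Within each context, layer 0 is the anchor
  representation, the adjacent layer 1 the positive, and a randomly chosen
  non-adjacent layer ($l \ge 2$) the negative. The printed loss has
  identical numerator and denominator summations — an evident typesetting
  corruption — so canonical InfoNCE is implemented exactly as the
  surrounding prose describes. With $L < 2$ there is no valid negative and
  the term is identically zero (a warning is raised).
* **Inter-graph.** For every layer $k$, the local layer-$k$ vector is the
  anchor, the matching non-local layer-$k$ vector the positive, and the
  remaining non-local layers the negatives. Negatives are drawn within
  the same anchor's layer stack only, as described; cross-node negatives
  exist behind a config switch, default off.

Both totals sum over the microbe side and the drug side; the source
description once sums the superscripts "M and N" and once "M and D",
which is read as notational inconsistency for the same two-sided sum.

### Objective, training and evaluation

Pair scores are $\hat y_{md} = \sigma(e_m^\top e_d)$ where $e_u$
concatenates the $L + 1$ local and $L + 1$ non-local layer vectors. The
training objective is

$$\mathcal{L} \;=\; \mathcal{L}_{\text{BCE}}
  \;+\; \lambda_{\text{intra}} \mathcal{L}_{\text{intra}}
  \;+\; \lambda_{\text{inter}} \mathcal{L}_{\text{inter}},$$

a combination whose weights are named in the source description's
hyperparameter analysis but whose formula is never printed; the weighted
sum above is the natural reading. Defaults $\lambda = 10^{-5}$ for both
terms follow the reported optimum for the larger of the two curated
datasets. Training uses Adam at learning rate 0.1 (unusually large for
Adam, but honoured as the stated protocol and exposed in the config),
batch size 64, at most 200 epochs, early stopping on validation AUC with
patience 10, and per-epoch 1:1 resampling of unknown pairs as negatives
(the cross-entropy sum is defined over a pair set whose negatives are
never specified). The validation set is 10% of the training positives
plus matched sampled negatives — the protocol mentions validation AUC
without defining the split. Contrastive terms are evaluated over the
anchors appearing in each mini-batch, the standard mini-batch treatment
of a sum over all nodes. In mini-batch SGD the validation positives
remain visible to graph construction; only *test* pairs are masked (see
below), so early stopping is mildly optimistic but never touches test
data.

Evaluation is balanced 5-fold cross-validation: positives are shuffled and
partitioned, each fold's test set pairs its positives with an equal number
of unknown pairs, and AUC (trapezoidal, tie-aware, equal to the
Mann-Whitney statistic) and AUPR (step-interpolated precision, which
avoids the optimism of trapezoidal PR interpolation) are averaged over
folds. **Leakage control:** each fold's test positives are zeroed out of
the interaction-matrix copy used for seed construction, similarity sets
and propagation during that fold — the evaluation protocol never states
this, but without it test labels leak through graph construction and
inflate every metric. Training negatives are drawn from the masked
matrix's zero entries, so a fold's test positives can occasionally be
sampled as training negatives; that is the honest positive-unlabelled
setting rather than leakage. Fold negatives are fixed once per fold by
seed, not resampled per run.

### Candidate ranking

`rank_candidates()` scores a query node against every counterpart,
excludes its known partners, and returns the top $k$ (default 20) by
descending score, ties broken by counterpart index for stable output.

## The synthetic benchmark

Because the curated datasets behind the published results require external
downloads and server-scale training, the package ships a generator whose
defaults define the study conditions used by the tests:
$100 \times 200$ interactions of expected density $0.05$ planted from a
rank-4 logistic factor model ($A_{md} \sim
\text{Bernoulli}(\sigma(s\,U_m^\top V_d + b))$, $U, V$ i.i.d. standard
normal, slope $s = 3$, bias $b$ solved by bisection to hit the target
density), plus a KG of one entity per microbe/drug and 300 attribute
entities with random unit latent directions. Every node links to the 8
attribute entities best aligned with its factor vector, in both edge
directions so that directed propagation can traverse
node-attribute-node paths — exactly the two-hop structure the layered
construction consumes — and 10% of link targets are rewired uniformly at
random. The logistic low-rank decoder mirrors the model's own
dot-product-plus-sigmoid scorer, making signal recovery a fair measure;
the generator does not attempt chemical structure, taxonomy, or the
dozens of relation types of real biomedical KGs, so passing tests
demonstrate signal recovery under the planted mechanism, not performance
on curated data.

## Numerical choices and problem sizes

* Softmax computations (attention, InfoNCE) use max-shift / log-sum-exp
  stabilization; predicted scores are clipped to $[10^{-12}, 1-10^{-12}]$
  inside the cross-entropy only.
* All sampling (fold splits, negative pairs, layer subsampling,
  contrastive negatives, corruption) is drawn from R's RNG under the
  configured seed; the C++ training core receives pre-drawn samples and is
  itself deterministic, so every run is bit-reproducible given its seed.
* Attention ties are impossible to break deterministically only through
  float equality; candidate ranking breaks score ties by index.
* The heavy loops (encoder forward/backward, Adam) are C++ (via
  RcppArmadillo) with the per-head query/key/value projections factored to
  the entity level once per batch — an algebraically identical
  rearrangement verified against the plain-R reference implementation in
  the test suite.
* The statistical checks (signal recovery, ablations) run the full
  pipeline at a desk scale chosen for a single CPU: embedding dimension
  32, 30 epochs, layer budget 8, batch size 256, TransE 30 epochs, three
  seeds; everything else at package defaults. At this scale one 5-fold
  cross-validation takes well under a minute.

## Known limitations

* Per-triple queries attend within a single layer only; no cross-layer or
  cross-anchor attention, and no relational-GAT-style variants.
* The intra-graph loss with the default $L = 3$ has only two candidate
  negative layers; its gradient signal is correspondingly weak at the
  default $\lambda = 10^{-5}$, and the ablation differences on synthetic
  data are small.
* Early stopping validates on pairs visible to graph construction (see
  above); test metrics are unaffected.
* The generator's attribute entities are sinks/sources of two-hop paths
  only; deeper KG motifs (chains through multiple attribute types) are
  not emulated.
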