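---
title: "Graph-convolutional label transfer: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional label transfer: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcnTransfer)
```

## The model

gcnTransfer treats label transfer as semi-supervised node classification.
Every cell — reference or query — is a node; reference nodes carry known
cell-type labels, query nodes do not. Two ingredients connect them:

* a **graph** encoding which cells look alike, built so that label
  information can only flow from reference cells *through* query cells
  (the reference–reference block of the adjacency is identically zero, and
  query cells are additionally wired to each other), and
* a **feature matrix** X of standardized expression over the selected genes,
  with columns ordered reference-then-query.

A two-layer graph convolutional network

$$\hat Y = \mathrm{softmax}\!\left(\tilde A\,\mathrm{ReLU}(\tilde A X^\top W^{(0)})\,W^{(1)}\right),
\qquad \tilde A = \check D^{-1/2}(A + I)\check D^{-1/2}$$

is trained by minimizing the cross-entropy summed over labeled nodes. Each
layer mixes a node's features with its neighbors' under the renormalized
adjacency $\tilde A$, whose self-loops keep isolated nodes well-defined and
whose symmetric degree scaling bounds the spectrum in $[-1, 1]$ (a property
the test suite verifies by dense eigendecomposition up to 500 nodes). After
training, a query cell receives the class whose posterior probability reaches
0.5; otherwise it stays `unassigned`.

### Assumptions

* Reference and query share enough biology that mutual nearest neighbors in
  a canonical-correlation space are mostly same-type pairs. Strong, global
  distributional shifts (platform, batch, modality) are tolerated because
  CCA only uses cross-dataset covariance of standardized genes; cell types
  present in only one dataset violate the assumption locally — which is
  exactly what the unknown screen looks for.
* Reference labels are trustworthy; the network never questions them.
* Genes discriminating the reference types also discriminate them in the
  query. Feature selection sees only the reference, so a query-only type is
  represented by whatever residual signal its cells carry on reference
  markers.

## Pipeline stages and their parameters

| stage | parameter | default | notes |
|---|---|---|---|
| feature selection | `max_features` | 2000 | one-way ANOVA F across reference types, Bonferroni-adjusted p < 0.05; fewer survive on small simulations (a warning reports the count) |
| standardization | `sd_type` | population | see "Numerical choices" |
| CCA | `k` | 20 | dimensions of the shared space; clamped to the achievable rank with a warning on tiny inputs |
| graphs | `n_neighbors` | 5 | used for both inter-dataset MNN and intra-query mutual kNN |
| network | `hidden_dims` | 32 | hidden width; `paper_hidden_dims` = {32, 64, 128, 256, 528, 1024} runs the full capacity sweep and keeps the best validation accuracy (ties to the smaller dim) |
| training | `lr`, `max_epochs`, `patience` | 0.01, 200, 10 | full-batch Adam; early stopping monitors validation loss and restores the best-validation weights |
| regularization | `dropout`, `weight_decay` | 0, 0 | available but off by default |
| assignment | `threshold` | 0.5 | at most one class can reach 0.5; exact ties go to the lower class index and are reported |
| unknown screen | `entropy_cutoff`, `enrichment_cutoff` | ½·log C, 2/C | see below |

The default hidden width is a single 32-unit layer: on the problem sizes this
package targets (hundreds to a few thousand cells, ≲ 2000 features) the
capacity sweep changes validation accuracy by little while multiplying the
cost; the sweep remains one argument away.

## The unknown-cell screen

Query cells are clustered by Louvain modularity on the intra-query graph.
For a cluster $h$, $m_{c,h}$ counts its cells linked by inter-dataset edges
to reference type $c$ (each cell counted once per type), and

$$S_{c,h} = \frac{m_{c,h}/\sum_c m_{c,h}}{n_c/\sum_c n_c},\qquad
H_h = -\sum_c p_c \log p_c,\; p_c = S_{c,h}/\Sigma S,\qquad
ES_h = \max_c S_{c,h} / \Sigma S.$$

A cluster of a known type links overwhelmingly to one reference type
($H \to 0$, $ES \to 1$); a novel type links sporadically to many
($H \to \log C$, $ES \to 1/C$). Clusters with **no** inter edges carry no
information and are assigned the boundary values $H = \log C$, $ES = 1/C$ by
convention and flagged. The flag cutoffs $H > \tfrac12\log C$ and $ES < 2/C$
are our own choice — no published thresholds exist — selected so that the two
analytic extremes (pure and link-free clusters) land on opposite sides for
every $C \ge 2$; both are arguments. Flags override the GCN assignment with
`"unknown"`, leaving the network untouched.

Because Louvain on a sparse mutual-kNN graph produces occasional singleton
clusters (an isolated vertex is its own community), a handful of ordinary
query cells may be conservatively relabeled unknown; they sit exactly at the
boundary convention above. Comparisons between novel and known clusters in
the tests therefore condition on clusters with measured (nonzero) link
profiles.

## Numerical choices

* **Standard deviation.** The per-gene scale $\rho_i$ divides by $n$
  (population form) by default; `sd_type = "sample"` switches to $n-1$. The
  choice only rescales rows by $\sqrt{n/(n-1)}$ and does not change CCA
  directions.
* **Zero-variance genes** cannot be standardized; they are dropped from both
  datasets (keeping the matrices row-aligned) with a warning. Genes constant
  across the whole reference get ANOVA p = 1 and are never selected.
* **CCA sign convention:** the largest-magnitude entry of each reference
  canonical vector is made positive, so results are reproducible across SVD
  implementations.
* **MNN ties** in neighbor ranks break deterministically by index
  (`ties.method = "first"`), making edge sets invariant to cell order.
* **Cross-entropy** is summed (not averaged) over labeled nodes, with the log
  argument clamped at 1e-12; the learning-rate default accounts for the sum
  scale.
* **Early stopping** monitors validation loss; validation *accuracy* decides
  the hidden-dim sweep, and the 10% test mask is only ever reported, never
  used for selection.
* **Determinism.** All randomness (splits, Glorot initialization, dropout,
  Louvain, region sampling) flows through one seed; repeated fits are
  bit-identical. Internally the RNG state of the caller is saved and
  restored.
* **Degenerate silhouettes:** singleton classes and coincident points get
  width 0.
* **Mixing-entropy regions** consist of a sampled cell plus its
  `n_neighbors − 1` nearest cells (the center is part of its own region), so
  a perfectly interleaved two-batch embedding attains the theoretical maximum
  $\log 2$ exactly.

## Open design points and how we resolved them

* **The intra-query graph.** Canonical correlation needs two datasets, so
  "project the query alone by CCA" is under-determined. Default: reuse the
  query-side canonical coordinates from the reference–query CCA, which keeps
  the intra and inter graphs in the same geometry. A fallback
  (`intra_mode = "svd"`) embeds the standardized query on its own top-k right
  singular vectors.
* **Neighborhood size** for both MNN graphs defaults to 5 and is shared; no
  published value exists, and the tests show the planted-cluster structure is
  recovered across a wide range.
* **Network depth.** The forward map above has two weight matrices
  (input→hidden→output); that is what we implement. Dropout and weight decay
  are provided but default off.
* **ANOVA input scale.** Values are used as provided; `log1p = TRUE` is
  available for raw counts with heavy tails.

## What the generator simulates — and what it does not

`simulate_pair()` draws per-gene baseline log-means N(0, 0.5²); each of 4
cell types elevates its own block of 25 marker genes by +2.0; counts are
lognormal-Poisson (overdispersion sd 0.3) with 20% Bernoulli dropout; the
query receives per-gene N(0, 0.5²) log-scale batch shifts; `novel_type` adds
one query-only type with its own marker block. Defaults give 75 cells per
type per dataset (300 + 300), the scale at which all stochastic checks run.

This emulates type-specific expression programs, multiplicative batch
effects and zero inflation. It does **not** emulate ambient RNA, doublets,
library-size gradients, correlated gene modules, continuous trajectories, or
realistic scATAC sparsity. Passing tests therefore demonstrate the machinery
is correct and robust to the modeled distortions — not that any particular
accuracy will be achieved on a given real dataset.

## Known limitations

* Dense linear algebra throughout: comfortable to a few thousand cells per
  dataset; beyond that, the all-pairs distance and SVD steps dominate.
* The unknown screen is cluster-level; a novel type that fails to form its
  own Louvain cluster will not be flagged.
* One-to-one homolog filtering discards paralog families entirely; this is
  deliberate (ambiguous mappings corrupt the cross-product) but loses genes.
* Accuracy on real cross-omics data depends on the query arriving as a
  gene-level activity matrix; converting peaks to gene activities is out of
  scope.
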