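# gcnTransfer

Cell-type label transfer across single-cell datasets with a semi-supervised
graph convolutional network (GCN).

## The problem

Annotating cells in a new single-cell experiment usually means re-clustering
and hand-curating marker genes. When a well-annotated **reference** dataset
exists — from the same tissue on another platform, another omics layer, or
even another species — its labels can instead be *transferred* to the
unlabeled **query** dataset. gcnTransfer does this for genes × cells
expression matrices, including cross-species runs via one-to-one homolog
tables, and it screens the query for cell types that are absent from the
reference rather than forcing every cell into a known class.

## The method

1. **Features.** Genes shared by both datasets are kept; a one-way ANOVA
   F-test across the reference cell types (Bonferroni-adjusted p < 0.05)
   ranks genes, and the top *m* (default 2000) are retained. Each gene row is
   standardized per dataset: x̃ᵢⱼ = (xᵢⱼ − x̄ᵢ)/ρᵢ.
2. **Hybrid graph.** The standardized datasets are projected into a shared
   *k*-dimensional space (default k = 20) by canonical correlation analysis,
   solved as the SVD of the cells × cells cross-product X̃ᵣᵀX̃_q. Mutual
   nearest neighbors (default 5) between reference and query coordinates give
   inter-dataset edges A^RQ; mutual kNN among the query coordinates gives
   intra-query edges A^QQ. The hybrid adjacency is the block matrix
   [0, A^RQ; (A^RQ)ᵀ, A^QQ].
3. **GCN.** With Ã = Ď^{-1/2}(A + I)Ď^{-1/2}, a two-layer network
   Ŷ = softmax(Ã · ReLU(Ã XᵀW⁽⁰⁾) · W⁽¹⁾) is trained by Adam
   (lr = 0.01, ≤ 200 epochs, early stopping with patience 10) on the masked
   cross-entropy over an 80/10/10 stratified split of the labeled reference
   cells. A query cell is assigned class *f* when ŷ ≥ 0.5, otherwise
   `unassigned`.
4. **Unknown screening.** Query cells are clustered by Louvain modularity on
   the intra graph; each cluster's inter-dataset links are summarized by the
   abundance-normalized enrichment S_c = (m_c/Σm)/(n_c/Σn), its entropy
   H = −Σ p log p and enrichment score ES = max S/ΣS. Clusters with
   H > ½·log C and ES < 2/C are relabeled `unknown`.
5. **Metrics.** Accuracy against supplied truth, batch-mixing entropy of the
   learned hidden embedding, and silhouette widths per cell type.

## Worked example

```r
library(gcnTransfer)

sim <- simulate_pair(sim_config(seed = 3))   # 4 types, 300 + 300 cells
fit <- gcn_transfer(sim$reference, sim$query, sim$ref_labels,
                    query_truth = sim$query_truth, seed = 3)
fit
#> Graph-convolutional label transfer
#>   300 reference + 300 query cells, 101 features, k = 20, hidden = 32
#>   query assignments:
#>
#>   type3   type4   type2   type1 unknown
#>      74      74      73      70       9
#>   accuracy vs supplied truth: 0.9700
```

The simulated query carries per-gene multiplicative batch shifts
(log-scale sd 0.5) and 20% dropout, yet 97% of the 300 query cells recover
their true type; a handful of weakly connected cells land in ambiguous
clusters and are conservatively relabeled `unknown`. `summary(fit)` adds the
per-cluster entropy/enrichment table, `predict(fit, threshold = ...)`
re-thresholds, `coef(fit)` returns the layer weights, and `plot(fit)` shows
the joint hidden embedding.

Real data come in through `read_mtx_matrix()` (10x-style MTX triplet),
`read_dense_matrix()` (CSV/TSV) and `read_cell_labels()`; cross-species runs
add `load_homolog_table()`. A thin command-line wrapper lives at
`inst/cli/gcn-transfer.R`.

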