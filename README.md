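# cbalign — cluster-guided batch alignment for single-cell RNA-seq

`cbalign` integrates two scRNA-seq batches while **preserving the cluster
structure of each batch**. Most integration methods match similar cells across
batches without using cell identity, which can over-align: biologically
distinct subpopulations get merged because the aligner only rewards mixing.
Here, each batch is first clustered on its own (Louvain on a kNN graph of
principal components); clusters are matched across batches; and a paired
autoencoder is trained so that only cells of *matched* clusters are pulled
together, cells of the same within-batch cluster stay close, and every cell's
expression profile remains reconstructable.

It is aimed at analysts integrating two batches of the same tissue measured
on different platforms (e.g. Smart-seq2 vs CEL-seq2 pancreas, Microwell-seq
vs FACS mouse lung) who care about keeping batch-specific substructure —
e.g. a subgroup of alpha cells present in only one batch — visible after
integration.

## The model

Clusters i (batch 1) and j (batch 2) are scored by their log mean cosine
distance over all cross-batch cell pairs,

    U[i, j] = log10( (1 / (k1_i * k2_j)) * sum_{p in i, q in j} d_cos(c1_p, c2_q) ),

and each batch-1 cluster is matched to its argmin column (directional map;
batch-2 clusters hit by no batch-1 cluster stay unmatched — the missing
cell-type case). Matched cell pairs get a weight `M = M1 * M2` combining
cluster-level closeness (normalized `-U`) with cell-level Euclidean
similarity; `M = 0` marks non-matched pairs.

A shared-weight autoencoder encodes the concatenation of one batch-1 and one
batch-2 cell to an embedding and decodes it back; two pairs (A&B, C&D) run
per step. With `d` input features per cell, the training loss is the
unweighted sum of

* reconstruction: `Lr = (1/2d) Σ((a1||c1 − A4||C4)²) + (1/2d) Σ((b1||d1 − B4||D4)²)`
* structure preserving: `Ls = (1/d) Σ((A4 − C4)²) · C¹[A,C] + (1/d) Σ((B4 − D4)²) · C²[B,D]`
* cluster preserving: `Lc = (1/d) Σ((A4 − B4)²) · M[A,B] + (1/d) Σ((C4 − D4)²) · M[C,D]`
* cluster prediction: `Lp = Σ_cells (1/K) Σ(softmax(recon) − one-hot label)²`

trained with Adam (lr 5e-4) and patience-based early stopping. Each cell's
final coordinates are the encoder output averaged over 16 random
matched-cluster partners from the other batch.

## Worked example

Simulate a realistic two-batch dataset (4 shared cell types, 300 cells per
batch, a strong cross-platform shift) and align it:

```r
library(cbalign)
sim <- generate_batches(scenario_presets()[["pancreas-like"]])
fit <- cba_align(sim$b1, sim$b2, min_cells_per_gene = 3,
                 hvg = list(n_top = 300), hidden_dims = 64, embed_dim = 16,
                 seed = 1)
summary(fit)
```

```
Cluster-guided batch alignment
Call: cba_align(b1 = sim$b1, b2 = sim$b2, min_cells_per_gene = 3, hvg = list(n_top = 300),
    hidden_dims = 64, embed_dim = 16, seed = 1)
  300 + 300 cells, 300 HVGs, 10 PCs, embedding dim 16
<cluster_match>: 4 batch-1 clusters, 4 batch-2 clusters
  match (b1 -> b2): 0 -> 0, 1 -> 2, 2 -> 1, 3 -> 3
  trained 1864 epochs (early stop); final losses Lr=12.9117 Ls=5.6574 Lc=1.5466 Lp=0.1693
<evaluation_report>
  kBET rejection: 0.405
  silhouette:     0.731
  NMI:            1.000
  ARI:            1.000
  FMI:            1.000
```

Reading the output: both batches were clustered into 4 Louvain clusters each
and matched one-to-one (the permutation `1 -> 2, 2 -> 1` is just label
order). After training, a fresh clustering of the aligned embedding agrees
perfectly with each batch's own clusters (NMI/ARI/FMI = 1), the embedding
clusters cleanly (silhouette 0.73), and the kBET rejection rate — the
fraction of cells whose local neighbourhood fails a chi-square test against
the global batch proportions — drops from 0.89 in the unaligned PC space to
0.41 (a low value means well-mixed batches; some residual structure is the
price of preserving per-batch clusters). `plot(fit)` shows the embedding and
the four loss trajectories; `predict`, `fitted` and `residuals` expose
embeddings and reconstructions.

The individual stages are exported too: `preprocess_batches()`,
`louvain_cluster()`, `cluster_distance_matrix()` / `match_clusters()` /
`inter_batch_weight_matrix()`, `paired_autoencoder()` / `fit_autoencoder()`,
`kbet_rejection()`, `silhouette_score()`, `ari()`, `nmi()`, `fmi()`, and the
generator `generate_batches()`. A thin command-line wrapper with
`simulate` / `align` / `evaluate` subcommands is installed at
`inst/scripts/cbalign`.

## Vignette

`vignettes/cluster-guided-alignment.Rmd` documents the model and its
assumptions, every tunable parameter with its default and rationale, the
synthetic generator's scope (what it does and does not emulate), numerical
choices (floors, tie-breaks, early stopping), and known limitations.
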