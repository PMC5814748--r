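# rwrsmooth

Network smoothing of single-cell gene expression by random walks with
restarts, with a robust consensus-clustering procedure and data-driven
selection of the smoothing strength.

## The problem

Single-cell RNA-seq quantifies every gene in every cell, but incomplete
transcript capture produces *dropouts*: false zero (or near-zero) counts for
genes that are actually expressed, most often for lowly expressed genes.
Dropout noise blurs cell-type structure and degrades clustering. Genes do
not act alone, however — they work in pathways and complexes — so a prior
gene–gene interaction network (e.g. STRING protein–protein interactions)
can be used to share signal between related genes: a gene with a spuriously
low count whose network neighbours are highly expressed gets pulled back up.

`rwrsmooth` is for analysts who want that prior-driven denoising step in
front of standard scRNA-seq workflows (clustering, embedding, annotation),
plus the machinery to evaluate whether it helped.

## The model

Let `A` be the column-normalized adjacency matrix of the gene network (each
gene's outgoing edge weights sum to 1) and `E` the genes × cells expression
matrix. A random walker on the network steps to a neighbour with
probability `α·A` and restarts at its origin with probability `1 − α`:

    f_{t+1} = α A f_t + (1 − α) f_0

The stationary distribution of this process defines the smoothing kernel

    K = (1 − α) (I − α A)⁻¹,     E_smoothed = K E

`α ∈ [0, 1)` controls how far expression diffuses; `α = 0` is no smoothing.
For an unsigned network, `K` is column-stochastic, so each cell's total
expression is conserved. Signed networks (inhibitory edges with negative
weights) are supported, with negative smoothed values clipped to zero.

Around the kernel the package provides:

* **Graph handling** — edge-list I/O, confidence-score percentile filtering
  (e.g. keep the 10 % most confident STRING interactions), column
  normalization, induced subgraphs, and label-shuffled null networks for
  sensitivity analysis.
* **Robust consensus clustering** — PAM over multiple reduced-dimension
  views (PCA or t-SNE of the 500 most variable genes, plus top-gene
  panels), K swept from 5 to 10, a cell × cell co-clustering matrix,
  consensus blocks with a minimum self-similarity (0.6) and size (20), and
  merging of blocks with < 10 % differentially expressed genes
  (Wilcoxon + BH, adjusted p < 0.05). Cells in no stable block stay
  unassigned.
* **Metrics** — per-cluster purity, adjusted mutual information (AMI,
  hypergeometric chance correction, max-entropy normalization), proportion
  of cells robustly clustered, and 20 × 20 grid entropy of 2D embeddings
  (also used to choose PCA vs t-SNE).
* **α selection** — `scan_alpha()` re-runs the clustering at each α on a
  grid and picks the α assigning the most cells to robust clusters;
  `pick_alpha_entropy()` is the label-free embedding-entropy alternative.
* **Synthetic benchmarks** — a stochastic-block-model gene network whose
  modules double as cell-type expression programs, negative-binomial
  counts, and expression-dependent logistic dropout, with full ground
  truth.

## Worked example

The default synthetic benchmark sits in the dropout-dominated regime:
300 genes in 6 network modules, 3 cell types, 150 cells, ~40 % zeros.

```r
library(rwrsmooth)

ds <- benchmark_instance("default")
ds
#> synthetic_dataset: 300 genes x 150 cells, 3 types, 39.9% zeros

rc_raw <- robust_cluster(ds$counts, seed = 1)
rc_raw
#> robust_clustering: 150 cells, 1 clusters, 13.3% assigned (tsne views)

smoothed <- netsmooth(ds$counts, ds$network, alpha = 0.8)
rc_sm <- robust_cluster(smoothed, seed = 1)
rc_sm
#> robust_clustering: 150 cells, 3 clusters, 77.3% assigned (pca views)

adjusted_mutual_information(rc_sm$labels, ds$true_labels)
#> [1] 1
cluster_purity(rc_sm$labels, ds$true_labels)$per_cluster
#> 1 2 3
#> 1 1 1
```

On the raw counts the consensus procedure finds a single unstable block
covering 13 % of cells (AMI 0 against the true types); after smoothing over
the prior network it recovers all three cell types exactly (AMI 1, every
cluster pure) and assigns 77 % of cells. The smoothing strength used above
is what `scan_alpha(ds$counts, ds$network, seed = 1)` selects by cluster
robustness, without looking at the true labels.

A thin command-line front end covering the same workflow (subcommands
`smooth`, `cluster`, `evaluate`, `scan-alpha`, `simulate`) is installed at
`system.file("cli", "rwrsmooth", package = "rwrsmooth")`.

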