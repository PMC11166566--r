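# seqspace

Sequence-informed co-embedding of cells and DNA k-mers for single-cell
ATAC-seq.

## The problem

scATAC-seq yields a very sparse binary matrix of cells × accessible events
(peaks or genomic tiles). Most embedding methods reduce that matrix alone and
discard the DNA underneath the events. `seqspace` learns a joint latent
space in which **cells and DNA k-mers live together**, by training on
sequences sampled from each cell's accessible events. Because any DNA
sequence can be projected into the same space, the trained model directly
supports transcription-factor motif activity scoring per cell, de novo motif
discovery, and co-embedding of multiple datasets through their shared
sequence features — no reference annotation or motif database is needed for
training itself.

It is aimed at regulatory-genomics analysts who have a peak/tile ×
cell matrix plus a reference genome, and want an embedding whose axes carry
sequence meaning.

## The model

A training example for an event is an `L = 150` bp subsequence sampled
uniformly from the event, encoded as a bag of features: its `L − k + 1`
canonical k-mers (`k = 8`; a k-mer and its reverse complement share one
embedding row) plus hashed k-mer pairs from every window of `N = 3`
consecutive k-mers. An entity of `M` features with rows `w_1..w_M` embeds as

```
E(bag) = (1 / M^P) * Σ w_i ,   P = 0.5
```

One cell with the event accessible is the positive; `K = 10` cells lacking
it are negatives (drawn within the positive's dataset, and batch when
batch-aware mode is on). Stochastic gradient descent minimizes the cosine
margin ranking loss

```
Loss = (1/K) Σ_k max(0, margin − cos(E, c_pos) + cos(E, c_neg_k))
```

over 20 examples per event per epoch for 50 epochs. Afterwards, TF activity
is the per-motif z-score across cells of `cos(cell, E(consensus k-mers))`;
clustering uses a shared-nearest-neighbor graph with Louvain communities; de
novo motifs come from clustering the 10-mers most associated with each cell
group in the latent space. A benchmarking module scores embeddings for
biological conservation (ASW/NMI/ARI/homogeneity) and batch correction
(batch ASW, graph connectivity, kBET, batch NMI), combines them as
`0.6·bio + 0.4·batch`, and compares methods by bootstrap with percentile-CI
inversion tests.

See `vignettes/seqspace-methods.Rmd` for the full methods account,
parameter table and design decisions.

## Worked example

The package ships a synthetic generator that plants a distinct 10-bp motif
in each cell type's specific events (300 cells, 3 types, 1000 events,
dropout 0.5):

```r
library(seqspace)

sim   <- simulate_benchmark()                       # frozen benchmark, seed 7
model <- train_embedding(sim$dataset, training_config(seed = 1))
model
#> seqspace_model: 300 cells x 30 dims; 2032896 feature rows (32896 k-mer + 2e+06 bucket)
#>   final epoch mean loss: 0.01535 (50 epochs)

graph <- build_graphs(model, K = 20)
res   <- resolution_search(graph, target_k = 3)
adjusted_rand_index(res$labels, sim$truth$cell_types)
#> [1] 1

scores <- tf_activity_scores(model, sim$truth$motifs)
round(sapply(split(seq_len(300), sim$truth$cell_types),
             function(i) colMeans(scores$scores[i, ])), 2)
#>               type1 type2 type3
#> planted_type1  1.35 -0.54 -0.81
#> planted_type2 -0.79  1.29 -0.50
#> planted_type3 -0.63 -0.73  1.35
```

Training takes about two minutes on one CPU. The Louvain clusters recover
the three planted types exactly (ARI = 1), and each planted motif's mean
activity z-score is highest in its own cell type (diagonal ≈ +1.3): cells
score high for a motif exactly when their accessible events carry its
sequence.

A thin command-line wrapper over the same functions is installed at
`inst/cli/seqspace` (subcommands `simulate`, `train`, `score`, `denovo`,
`bench`).

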