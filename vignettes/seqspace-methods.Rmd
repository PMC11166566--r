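---
title: "seqspace: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqspace: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`seqspace` learns a joint latent space for the cells of a scATAC-seq
experiment and the DNA k-mers of its accessible regions. The only inputs are
a binary cell-by-event matrix (events are peaks or tiles) and the DNA
sequence of each event; no reference annotation, motif database or prior
dimensionality reduction is involved in training.

Training streams examples. For each example, an `L = 150` bp subsequence is
sampled uniformly from one event (events shorter than `L` are used whole) and
represented as a bag of features:

* its `L - k + 1` overlapping k-mers (`k = 8`), where a k-mer and its reverse
  complement share one embedding row (canonical hashing), and
* for every window of `N = 3` consecutive retained k-mers, each of the three
  k-mer pairs inside the window, hashed into a fixed number of `bucket` rows
  (2,000,000 by default). The pair hash satisfies
  `h(a, b) = h(revcomp(b), revcomp(a))`, so the full feature bag of a
  sequence equals that of its reverse complement as a multiset.

An entity made of `M` features with rows `w_1..w_M` is embedded as
`sum(w_i) / M^P` with `P = 0.5`. The sampled sequence is the left-hand side
of the example; one cell in which the event is accessible is the positive
right-hand side; `K_neg = 10` cells lacking the event are negatives, drawn
uniformly without replacement from the positive cell's dataset (and batch,
when batch-aware training is enabled). The loss per example is the margin
ranking loss

```
Loss = (1/K) * sum_k max(0, margin - cos(lhs, pos) + cos(lhs, neg_k))
```

with `margin = 0.05`. Gradients flow to the positive cell row, to negative
rows whose hinge is positive (a zero-loss negative is untouched), and to all
feature rows of the bag scaled by `1/M^P`. Cells and sequences end up
comparable by cosine similarity in one space, which is what all downstream
operations use.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 30 | latent dimension |
| `L` | 150 bp | sampled subsequence length |
| `k` | 8 bp | k-mer length (supported range 1–12) |
| `N` | 3 | context window, in consecutive k-mers |
| `bucket` | 2,000,000 | hash rows for k-mer-pair features |
| `P` | 0.5 | entity normalization exponent |
| `epochs` | 50 | passes over the event set |
| `examples_per_event` | 20 | sampled examples per event per epoch |
| `K_neg` | 10 | negatives per example |
| `margin` | 0.05 | hinge margin |
| `lr0` | 0.01 | initial learning rate, decaying linearly to 0 |

`d`, `L`, `k`, `N`, `P`, `epochs` and `examples_per_event` are the
conventional operating point for StarSpace-style sequence embeddings of
accessibility data. `K_neg`, `margin` and `lr0` take the standard defaults
of that trainer family; all are exposed in `training_config()`.

## Numerical and design choices

**Optimizer.** The default is plain SGD with a per-example learning rate
decaying linearly to zero over the planned number of examples — the
behaviour of the C++ StarSpace trainer. A per-row Adagrad variant
(`optimizer = "adagrad"`) is available but not the default: on the synthetic
benchmark its per-row accumulators inflate during the noisy early phase and
then suppress later refinement, which measurably loosens within-type
coherence of the cell embeddings.

**Precision.** Embeddings are stored in single precision inside the trainer
(as StarSpace does); accumulations (entity sums, norms, dot products,
gradients) are carried in double precision. Training is single-threaded and
bit-reproducible for a fixed `seed`.

**Strand handling.** Event sequences are canonicalized at load time to the
lexicographic minimum of the sequence and its reverse complement, and
feature rows are summed and updated in sorted row order. Together these make
training exactly invariant to reverse-complementing any input sequence —
same loss trace, same embeddings — which is the natural contract for
unstranded accessibility data.

**Initialization.** Cell and canonical k-mer rows start i.i.d. uniform in
`[-1/d, 1/d]`. Hashed bucket rows start at exactly zero: a hashed pair
feature that never occurs in training then contributes nothing to an induced
embedding (rather than random noise), and model serialization can omit
untouched rows. Zero rows receive gradients like any other row once their
feature occurs.

**Zero-norm cosine.** The cosine of a zero vector with anything is defined
as 0 (and counted in a diagnostic), which avoids NaNs in the first updates.

**Ambiguous bases.** Any k-window containing a non-ACGT character is
skipped; soft-masked (lowercase) genome sequence is uppercased and used.
Only full windows of `N` retained k-mers generate pair features, and
repeated pairs from overlapping windows are kept as repeated features.

**k ≤ 12.** The canonical-index lookup table and the exact modular
arithmetic of the pair hash (valid below 2^53 in double precision on the R
side) cap the supported k-mer length at 12; practical settings use 6–10.

## Downstream analyses

**TF activity.** A motif's consensus (per-column argmax, ties A<C<G<T) is
embedded from its `width - k + 1` constituent k-mers only — no pair features,
matching the consensus k-mer count — and cosine similarity to every cell is
z-scored per motif across cells (population SD). A flag
(`use_ngrams = TRUE`) enables the alternative reading that treats the
consensus like any other sequence entity, including pair features.

**Graphs and clustering.** Exact brute-force KNN (cosine by default,
`K = 20`), SNN weights as Jaccard overlap of the K-neighborhoods including
self, pruned below 1/15, Louvain communities via igraph at a given
resolution. `resolution_search()` scans a grid for the number of clusters
matching the number of cell types and falls back to
`merge_small_clusters()` — wholesale reassignment of the smallest cluster to
its most SNN-connected larger neighbor — when the grid only overshoots.
Exact KNN is capped at 20,000 cells; larger inputs should be subsampled.

**De novo motifs.** All canonical 10-mers are embedded as the plain average
of their three constituent 8-mer rows; each cell's `K = 50` nearest 10-mers
(cosine) are collected; a 10-mer is associated with a group of cells when it
is a neighbor of at least 20% of them; associated 10-mers are clustered at
dissimilarity `1 - best ungapped overlap matches/10` (over all offsets and
both strands, average linkage, cut at 0.5), and clusters of more than three
10-mers are star-aligned against their medoid to produce a PWM (pseudocount
0.01, columns covered by at least half the members). Comparable pipelines
delegate the clustering and alignment steps to kmer::cluster and ClustalW;
the dissimilarity and star alignment used here are deterministic,
strand-aware equivalents with the cut height kept at 0.5 on the normalized
scale.

**Benchmarking.** Biological conservation is the mean of rescaled cell-type
ASW `(s+1)/2`, NMI (arithmetic normalization), ARI (clipped to [0,1]) and
homogeneity. Batch correction is the mean of per-type batch ASW `1-|s|`,
per-type KNN-subgraph largest-component fraction, per-type kBET acceptance
(chi-squared goodness of fit of neighborhood batch composition at
alpha = 0.05, neighborhood size `min(50, floor(mean batch size/2))`, at most
1000 tested cells) and per-type `1 - NMI(cluster, batch)`. The overall score
is `0.6*bio + 0.4*batch`. Bootstrap comparison applies the same resampled
cell indices to every method, re-clusters each resample at the resolution
found on the full data (re-searching inside every replicate would be
1,000-fold costlier, so the full-data resolution is reused), and derives
two-sided p-values by percentile-CI inversion with Benjamini–Hochberg
adjustment across method pairs. Cell
types present in a single batch are excluded from the batch metrics with a
warning; with a single batch overall the mixing scores are 1 by convention.

## The synthetic benchmark

`simulate_dataset()` generates fully self-contained data with known truth:
uniform-ACGT event sequences; half the events type-specific (each carrying
its type's 10-bp consensus, mutated at 5% per position, inserted at a
uniform position in 90% of them), 20% shared (open probability 0.3), 10%
batch-artifact when more than one batch is requested (open at
`plogis(qlogis(0.1) + batch_strength)` in the favored batch versus 0.1),
the rest background (0.05). Type-specific events are open in their own
type's cells with probability `1 - dropout` and elsewhere with 0.02. Five
percent of events are 100 bp (shorter than `L`) to exercise the short-event
rule. The frozen benchmark (`default_benchmark_config()`) uses 300 cells, 3
types, 1000 events of 500 bp, insert rate 0.9, dropout 0.5, 2 batches, seed
7 — small enough to train in about two minutes on one CPU, which is the
problem size all heavy tests and the acceptance script use.

What the generator does **not** emulate: GC composition and repeat structure
of real genomes, fragment-level counts, co-accessibility beyond the planted
block structure, peak-width variation beyond the short-event flag, and
doublets. Passing the recovery tests therefore shows the algorithm works as
specified, not that it would match results on real atlases.

A consequence of the uniform-background design worth knowing: every k-mer of
a type-specific event is equally predictive of the type — not just the
planted motif — so per-cell 10-mer neighborhoods contain many event-specific
sequences alongside motif variants. The planted-motif *activity scoring*
test separates types cleanly under these conditions, while de novo recovery
operates close to its detection limit at 300 cells and 1000 events (real
applications of this procedure use one to two orders of magnitude more
sequence and cells).

Batch effects are modeled purely as batch-favored accessibility (artifact
events), per the generator's contract. Under this model the batch signal
enters the embedding through positive-example pulls, which negative-sampling
policy cannot remove; restricting negatives to the positive's batch
(batch-aware training) additionally gives each artifact event a pure
within-batch discrimination task. Both effects are visible in the
benchmark's batch scores, and the acceptance suite measures the batch-aware
versus non-aware comparison directly rather than assuming its sign.

## Known limitations

* Single-threaded training only; the determinism contract is prioritized
  over wall-clock scaling. The frozen benchmark trains in ~2 minutes; a
  700k-cell atlas would not be practical without the parallel trainer of the
  original C++ implementation.
* Composite/dimeric motifs are not specially handled by consensus-based
  activity scoring.
* Exact KNN only (20,000-cell cap) — no approximate index is bundled.
* The de novo tree-cut threshold (0.5) is conventionally quoted for a
  different underlying k-mer metric; its equivalence on the normalized
  overlap dissimilarity used here is assumed, not established.
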