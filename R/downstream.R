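## downstream: motif consensus embedding, TF activity scores, KNN/SNN graphs,
## Louvain clustering utilities, joint cell + TF tables.

#' Consensus sequence of a motif
#'
#' Per PWM column, the maximum-probability base; ties are broken by the fixed
#' base order A < C < G < T.
#'
#' @param motif a `motif_model`, or a 4 x width PWM matrix.
#' @param min_width minimum acceptable width (error below; default 1).
#' @return consensus DNA string.
#' @export
motif_consensus <- function(motif, min_width = 1L) {
  pwm <- if (inherits(motif, "motif_model")) motif$pwm else motif
  if (nrow(pwm) != 4L) stop("PWM must have 4 rows")
  if (ncol(pwm) < min_width)
    stop("motif width ", ncol(pwm), " is below the required ", min_width)
  paste(DNA_BASES[apply(pwm, 2L, which.max)], collapse = "")
}

#' Embed a motif consensus in the model space
#'
#' The consensus sequence is represented as the bag of its
#' `width - k + 1` constituent canonical k-mers only (no pair context
#' features, matching the consensus k-mer count), and embedded as
#' `sum(w_i) / M^P`. Set `use_ngrams = TRUE` for the alternative reading that
#' includes hashed pair features, as for any other sequence entity.
#'
#' @param motif a `motif_model`, or a consensus DNA string.
#' @param model a trained `seqspace_model`.
#' @param use_ngrams include hashed pair-context features (default `FALSE`).
#' @return numeric d-vector.
#' @export
embed_motif <- function(motif, model, use_ngrams = FALSE) {
  stopifnot(inherits(model, "seqspace_model"))
  spec <- model$spec
  consensus <- if (inherits(motif, "motif_model"))
    motif_consensus(motif, min_width = spec$k) else toupper(motif)
  if (nchar(consensus) < spec$k)
    stop("motif width ", nchar(consensus), " is shorter than k = ", spec$k)
  if (use_ngrams) {
    bag <- feature_bag(consensus, spec)
    if (bag$M == 0L) stop("all consensus windows are ambiguous")
    return(induced_embedding(bag, model$feature_embeddings, spec$P))
  }
  idx <- kmer_bag(consensus, spec)
  if (!length(idx)) stop("all consensus windows are ambiguous")
  induced_embedding(idx, model$feature_embeddings, spec$P)
}

#' Per-cell TF activity scores
#'
#' Cosine similarity between every cell embedding and every motif consensus
#' embedding, z-scored across cells per motif (population SD). Motifs that
#' fail to embed are dropped with a warning; a constant raw column becomes an
#' all-zero score column and is recorded in attribute `"constant_motifs"`.
#'
#' @param model a trained `seqspace_model` with at least 2 cells.
#' @param motifs a list of `motif_model` objects.
#' @param use_ngrams passed to [embed_motif()].
#' @return list with `scores` (cells x motifs z-scores) and `raw` (cosine
#'   similarities), class `tf_score_matrix`.
#' @export
tf_activity_scores <- function(model, motifs, use_ngrams = FALSE) {
  stopifnot(inherits(model, "seqspace_model"))
  if (nrow(model$cell_embeddings) < 2L) stop("need at least 2 cells")
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  names(motifs) <- vapply(motifs, `[[`, "", "name")
  emb <- lapply(motifs, function(m) {
    tryCatch(embed_motif(m, model, use_ngrams = use_ngrams),
             error = function(e) {
               warning("motif '", m$name, "' dropped: ", conditionMessage(e))
               NULL
             })
  })
  keep <- !vapply(emb, is.null, logical(1L))
  if (!any(keep)) stop("no motif could be embedded")
  memb <- do.call(rbind, emb[keep])
  raw <- cosine_similarity(model$cell_embeddings, memb)
  dimnames(raw) <- list(model$cell_ids, names(motifs)[keep])
  sds <- apply(raw, 2L, stats::sd) * sqrt((nrow(raw) - 1) / nrow(raw))
  constant <- sds < 1e-12
  scores <- sweep(raw, 2L, colMeans(raw), "-")
  scores[, !constant] <- sweep(scores[, !constant, drop = FALSE], 2L,
                               sds[!constant], "/")
  scores[, constant] <- 0
  if (any(constant))
    warning("constant raw similarity for: ",
            paste(colnames(raw)[constant], collapse = ", "))
  structure(list(scores = scores, raw = raw,
                 constant_motifs = colnames(raw)[constant]),
            class = "tf_score_matrix")
}

#' Nearest-neighbor and shared-nearest-neighbor graphs
#'
#' Exact brute-force K-nearest neighbors under cosine (default) or euclidean
#' distance, and the SNN graph with Jaccard weights over the K-neighborhoods
#' including self: `w(u,v) = |N(u) n N(v)| / |N(u) u N(v)|`, pruned below
#' 1/15. Exact search is used throughout and capped at 20,000 cells.
#'
#' @param x a `seqspace_model` or a cells x d embedding matrix.
#' @param K neighbors per cell (default 20).
#' @param metric `"cosine"` or `"euclidean"`.
#' @param prune SNN weights strictly below this are dropped (default 1/15).
#' @return an object of class `cell_graph`: `knn` (n x K integer matrix,
#'   self excluded), `snn` (sparse symmetric weight matrix), `K`, `metric`.
#' @export
build_graphs <- function(x, K = 20L, metric = c("cosine", "euclidean"),
                         prune = 1 / 15) {
  metric <- match.arg(metric)
  emb <- if (inherits(x, "seqspace_model")) x$cell_embeddings else as.matrix(x)
  n <- nrow(emb)
  if (K >= n) stop("K must be smaller than the number of cells")
  if (n > 20000L)
    stop("exact KNN is capped at 20,000 cells; subsample or cluster in blocks")
  if (metric == "cosine") {
    dmat <- 1 - cosine_similarity(emb, emb)
  } else {
    dmat <- as.matrix(stats::dist(emb))
  }
  diag(dmat) <- Inf
  ord <- apply(dmat, 1L, function(r) order(r)[seq_len(K)])
  knn <- if (is.matrix(ord)) t(ord) else matrix(ord, ncol = 1L)
  # neighborhood = self + K nearest
  nb_i <- rep(seq_len(n), each = K + 1L)
  nb_j <- as.integer(t(cbind(seq_len(n), knn)))
  A <- Matrix::sparseMatrix(i = nb_i, j = nb_j, x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)
  inter <- methods::as(methods::as(inter, "generalMatrix"), "CsparseMatrix")
  u <- 2 * (K + 1L) - inter@x
  w <- inter@x / u
  snn <- inter
  snn@x <- w
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  Matrix::diag(snn) <- 0
  snn <- Matrix::drop0(snn)
  rownames(snn) <- colnames(snn) <- rownames(emb)
  structure(list(knn = knn, snn = snn, K = as.integer(K), metric = metric,
                 n = n),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph: %d cells, K=%d (%s), %d SNN edges\n",
              x$n, x$K, x$metric, length(x$snn@x) / 2L))
  invisible(x)
}

#' Louvain clustering on the SNN graph
#'
#' Modularity-based community detection (multilevel/Louvain, delegated to
#' igraph) at a given resolution; deterministic for a fixed `seed`.
#'
#' @param graph a `cell_graph` from [build_graphs()].
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed for the community detection.
#' @return integer cluster labels (1-based).
#' @export
cluster_cells <- function(graph, resolution = 0.8, seed = 0L) {
  stopifnot(inherits(graph, "cell_graph"))
  if (graph$n == 0L) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(graph$snn, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(comm))
}

#' Merge small clusters into their SNN-nearest larger clusters
#'
#' Iteratively takes the smallest cluster below `min_size` (or, with
#' `target_k`, the smallest cluster while more than `target_k` clusters
#' remain) and reassigns it wholesale to the cluster with the largest mean
#' inter-cluster SNN weight. Connectivity ties are broken toward the larger
#' cluster, then the lower label. The number of clusters never increases.
#'
#' @param labels integer cluster labels.
#' @param snn the SNN weight matrix (from [build_graphs()]).
#' @param min_size clusters smaller than this are merged away.
#' @param target_k alternatively, merge until this many clusters remain.
#' @return relabeled integer vector (labels compacted to 1..k).
#' @export
merge_small_clusters <- function(labels, snn, min_size = NULL, target_k = NULL) {
  if (is.null(min_size) && is.null(target_k))
    stop("supply min_size or target_k")
  labels <- as.integer(factor(labels))
  if (inherits(snn, "cell_graph")) snn <- snn$snn
  repeat {
    sizes <- table(labels)
    k <- length(sizes)
    if (k < 2L) break
    needs_merge <- if (!is.null(target_k)) k > target_k
                   else min(sizes) < min_size
    if (!needs_merge) break
    smallest <- as.integer(names(sizes)[order(sizes, as.integer(names(sizes)))[1L]])
    members <- which(labels == smallest)
    others <- setdiff(as.integer(names(sizes)), smallest)
    conn <- vapply(others, function(o) {
      om <- which(labels == o)
      sum(snn[members, om, drop = FALSE]) / (length(members) * length(om))
    }, numeric(1L))
    best <- max(conn)
    cand <- others[conn >= best - 1e-15]
    if (length(cand) > 1L) {
      cs <- sizes[as.character(cand)]
      cand <- cand[cs == max(cs)]
      cand <- min(cand)
    }
    labels[members] <- cand
  }
  as.integer(factor(labels))
}

#' Joint cell + TF embedding table
#'
#' Concatenates selected motif embeddings to the cell embeddings and returns
#' the combined matrix with typed row labels plus the pairwise cosine
#' distances, ready for any 2-D embedder (the 2-D projection itself is left
#' to the caller).
#'
#' @param model a trained `seqspace_model`.
#' @param motifs list of `motif_model` objects (possibly empty).
#' @param use_ngrams passed to [embed_motif()].
#' @return list with `embedding` ((n_cells + n_motifs) x d), `type`
#'   (`"cell"`/`"motif"`), and `distance` (a `dist` of cosine distances).
#' @export
joint_cell_tf_table <- function(model, motifs = list(), use_ngrams = FALSE) {
  stopifnot(inherits(model, "seqspace_model"))
  if (inherits(motifs, "motif_model")) motifs <- list(motifs)
  memb <- NULL
  if (length(motifs)) {
    rows <- lapply(motifs, embed_motif, model = model, use_ngrams = use_ngrams)
    memb <- do.call(rbind, rows)
    rownames(memb) <- paste0("motif:", vapply(motifs, `[[`, "", "name"))
  }
  cells <- model$cell_embeddings
  rownames(cells) <- paste0("cell:", model$cell_ids)
  emb <- rbind(cells, memb)
  dmat <- 1 - cosine_similarity(emb, emb)
  list(embedding = emb,
       type = c(rep("cell", nrow(cells)), rep("motif", length(motifs))),
       distance = stats::as.dist(dmat))
}
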