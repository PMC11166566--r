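## benchmark: clustering-agreement and batch-mixing metrics, the weighted
## overall score, resolution search, and bootstrap method comparison.

## --- elementary metrics -----------------------------------------------------

entropy_of <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' Mutual information normalized by the arithmetic mean of the label
#' entropies. When both labelings are constant the score is 1; when exactly
#' one is constant it is 0.
#'
#' @param a,b label vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  ha <- entropy_of(a); hb <- entropy_of(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Adjusted Rand index
#'
#' @param a,b label vectors of equal length.
#' @return ARI (can be negative for worse-than-chance agreement).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' Homogeneity
#'
#' `1 - H(classes | clusters) / H(classes)`: 1 when every cluster contains a
#' single class; 1 by convention when the classes are constant.
#'
#' @param classes ground-truth labels.
#' @param clusters predicted cluster labels.
#' @return homogeneity in \[0, 1\].
#' @export
homogeneity <- function(classes, clusters) {
  stopifnot(length(classes) == length(clusters))
  hc <- entropy_of(classes)
  if (hc == 0) return(1)
  tab <- table(classes, clusters)
  n <- length(classes)
  pk <- colSums(tab) / n
  hck <- 0
  for (j in seq_len(ncol(tab))) {
    p <- tab[, j] / sum(tab[, j])
    p <- p[p > 0]
    hck <- hck - pk[j] * sum(p * log(p))
  }
  max(0, min(1, 1 - hck / hc))
}

#' Silhouette widths
#'
#' Per-sample silhouette `s = (b - a) / max(a, b)` with `a` the mean
#' within-cluster distance (self excluded) and `b` the smallest mean distance
#' to another cluster; singletons get 0.
#'
#' @param embedding samples x d matrix, or a precomputed distance matrix
#'   (when `is_dist = TRUE`).
#' @param labels cluster labels.
#' @param metric `"euclidean"` or `"cosine"` (ignored for `is_dist`).
#' @param is_dist `embedding` is already a full distance matrix.
#' @return numeric vector of silhouette widths.
#' @export
silhouette_widths <- function(embedding, labels, metric = "euclidean",
                              is_dist = FALSE) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("silhouette needs at least 2 clusters")
  D <- if (is_dist) as.matrix(embedding)
       else if (metric == "cosine") 1 - cosine_similarity(embedding, embedding)
       else as.matrix(stats::dist(embedding))
  n <- nrow(D)
  G <- stats::model.matrix(~ 0 + factor(labels))
  sizes <- colSums(G)
  sums <- D %*% G                       # n x k: total distance to each cluster
  own <- match(labels, levels(factor(labels)))
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[own[i]]
    a[i] <- if (ni > 1) sums[i, own[i]] / (ni - 1) else NA_real_
    b[i] <- min(sums[i, -own[i]] / sizes[-own[i]])
  }
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  s[!is.finite(s)] <- 0
  s
}

## largest-connected-component fraction of the KNN graph over given rows
knn_lcc_fraction <- function(embedding, K, metric = "cosine") {
  n <- nrow(embedding)
  if (n == 1L) return(1)
  Kuse <- min(K, n - 1L)
  g <- build_graphs(embedding, K = Kuse, metric = metric)
  el <- cbind(rep(seq_len(n), each = Kuse), as.integer(t(g$knn)))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(ig)
  max(comp$csize) / n
}

## --- composite scores -------------------------------------------------------

#' Biological conservation scores
#'
#' Four metrics of agreement between an embedding/clustering and ground-truth
#' cell types: cell-type ASW rescaled to \[0,1\] as `(mean silhouette + 1)/2`
#' (euclidean distance on the embedding), NMI, ARI (clipped to \[0,1\]) and
#' homogeneity between cluster labels and cell types; `mean` is their
#' average.
#'
#' @param embedding cells x d matrix.
#' @param cluster_labels predicted clusters.
#' @param cell_types ground-truth labels.
#' @return list `asw`, `nmi`, `ari`, `homogeneity`, `mean`.
#' @export
bio_conservation <- function(embedding, cluster_labels, cell_types) {
  if (length(unique(cell_types)) < 2L)
    stop("silhouette undefined with a single cell type")
  asw <- (mean(silhouette_widths(embedding, cell_types)) + 1) / 2
  out <- list(
    asw = asw,
    nmi = nmi(cluster_labels, cell_types),
    ari = max(0, min(1, adjusted_rand_index(cluster_labels, cell_types))),
    homogeneity = homogeneity(cell_types, cluster_labels)
  )
  out$mean <- mean(unlist(out))
  out
}

#' Batch correction scores
#'
#' Four batch-mixing metrics averaged into `mean`:
#' * `batch_asw`: per cell type, mean of `1 - |silhouette(batch)|` over the
#'   type's cells, averaged over types with >= 2 batches;
#' * `graph_connectivity`: per cell type, the fraction of its cells in the
#'   largest connected component of the type's KNN subgraph, averaged;
#' * `kbet_acceptance`: per cell type, the fraction of tested neighborhoods
#'   (size `min(50, floor(mean batch size / 2))`, at most 1000 tested cells)
#'   whose batch composition passes a chi-squared goodness-of-fit test
#'   against the type's batch proportions at alpha = 0.05, averaged;
#' * `batch_nmi`: per cell type, `1 - NMI(cluster labels, batch)`, averaged.
#'
#' Cell types present in a single batch are excluded from `batch_asw`, kBET
#' and `batch_nmi` with a warning. With a single batch overall, all mixing
#' scores are 1 by convention.
#'
#' @param embedding cells x d matrix.
#' @param batches per-cell batch labels.
#' @param cell_types per-cell type labels.
#' @param cluster_labels cluster assignments (for `batch_nmi`).
#' @param K neighbors for the connectivity graph (default 20).
#' @param max_tested kBET neighborhood sample cap (default 1000).
#' @param seed RNG seed for the kBET cell sample.
#' @return list `batch_asw`, `graph_connectivity`, `kbet_acceptance`,
#'   `batch_nmi`, `mean`.
#' @export
batch_correction_scores <- function(embedding, batches, cell_types,
                                    cluster_labels, K = 20L,
                                    max_tested = 1000L, seed = 0L) {
  batches <- as.character(batches)
  types <- unique(as.character(cell_types))
  n_batches_total <- length(unique(batches))

  gc_per_type <- vapply(types, function(t) {
    knn_lcc_fraction(embedding[cell_types == t, , drop = FALSE], K)
  }, numeric(1L))
  graph_connectivity <- mean(gc_per_type)

  if (n_batches_total < 2L) {
    return(list(batch_asw = 1, graph_connectivity = graph_connectivity,
                kbet_acceptance = 1, batch_nmi = 1,
                mean = mean(c(1, graph_connectivity, 1, 1))))
  }

  eligible <- types[vapply(types, function(t) {
    length(unique(batches[cell_types == t])) >= 2L
  }, logical(1L))]
  if (length(eligible) < length(types))
    warning("cell type(s) in a single batch excluded from batch metrics: ",
            paste(setdiff(types, eligible), collapse = ", "))
  if (!length(eligible))
    stop("no cell type spans more than one batch")

  asw_per_type <- vapply(eligible, function(t) {
    idx <- cell_types == t
    s <- silhouette_widths(embedding[idx, , drop = FALSE], batches[idx])
    mean(1 - abs(s))
  }, numeric(1L))

  nk <- max(5L, min(50L, floor(mean(table(batches)) / 2)))
  kbet_per_type <- vapply(eligible, function(t) {
    idx <- which(cell_types == t)
    emb_t <- embedding[idx, , drop = FALSE]
    bt <- batches[idx]
    props <- table(bt) / length(bt)
    nk_t <- min(nk, length(idx) - 1L)
    if (nk_t < length(props)) return(NA_real_)
    dmat <- 1 - cosine_similarity(emb_t, emb_t)
    diag(dmat) <- -1  # self is its own nearest neighbor
    tested <- seq_along(idx)
    if (length(tested) > max_tested)
      tested <- with_seed(seed, sample(tested, max_tested))
    acc <- vapply(tested, function(i) {
      nb <- order(dmat[i, ])[seq_len(nk_t)]
      counts <- table(factor(bt[nb], levels = names(props)))
      p <- suppressWarnings(stats::chisq.test(counts, p = as.numeric(props))$p.value)
      as.numeric(p >= 0.05)
    }, numeric(1L))
    mean(acc)
  }, numeric(1L))
  kbet <- mean(kbet_per_type, na.rm = TRUE)
  if (all(is.na(kbet_per_type))) kbet <- NA_real_

  bnmi_per_type <- vapply(eligible, function(t) {
    idx <- cell_types == t
    1 - nmi(cluster_labels[idx], batches[idx])
  }, numeric(1L))

  out <- list(batch_asw = mean(asw_per_type),
              graph_connectivity = graph_connectivity,
              kbet_acceptance = kbet,
              batch_nmi = mean(bnmi_per_type))
  out$mean <- mean(unlist(out), na.rm = TRUE)
  out
}

#' Weighted overall score
#'
#' `0.6 * bio_mean + 0.4 * batch_mean`.
#'
#' @param bio_mean biological-conservation mean score in \[0, 1\].
#' @param batch_mean batch-correction mean score in \[0, 1\].
#' @return the weighted average.
#' @export
overall_score <- function(bio_mean, batch_mean) {
  stopifnot(bio_mean >= 0, bio_mean <= 1, batch_mean >= 0, batch_mean <= 1)
  0.6 * bio_mean + 0.4 * batch_mean
}

#' Search Louvain resolutions for a target cluster count
#'
#' Clusters the SNN graph over a resolution grid and returns the first
#' resolution yielding exactly `target_k` clusters. If none does and some
#' candidate exceeds `target_k`, the closest-above candidate is reduced with
#' [merge_small_clusters()]; if every candidate falls below `target_k`, an
#' error suggests a finer or higher grid.
#'
#' @param graph a `cell_graph`.
#' @param target_k desired number of clusters (>= 2).
#' @param resolutions resolution grid (default `seq(0.1, 2, by = 0.1)`).
#' @param seed clustering seed.
#' @return list with `resolution`, `labels`, `merged` (logical).
#' @export
resolution_search <- function(graph, target_k,
                              resolutions = seq(0.1, 2, by = 0.1),
                              seed = 0L) {
  stopifnot(target_k >= 2L)
  counts <- integer(length(resolutions))
  labs <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    labs[[i]] <- cluster_cells(graph, resolution = resolutions[i], seed = seed)
    counts[i] <- length(unique(labs[[i]]))
    if (counts[i] == target_k)
      return(list(resolution = resolutions[i], labels = labs[[i]],
                  merged = FALSE))
  }
  above <- which(counts > target_k)
  if (!length(above))
    stop("no resolution in the grid reached ", target_k,
         " clusters; try a finer or higher grid")
  pick <- above[which.min(counts[above])]
  merged <- merge_small_clusters(labs[[pick]], graph$snn, target_k = target_k)
  list(resolution = resolutions[pick], labels = merged, merged = TRUE)
}

## --- bootstrap --------------------------------------------------------------

#' Percentile confidence interval
#'
#' @param x bootstrap draws of a statistic.
#' @param alpha 1 - confidence level.
#' @return numeric `c(lower, upper)` (the `alpha/2` and `1 - alpha/2`
#'   quantiles).
#' @export
percentile_ci <- function(x, alpha = 0.05) {
  stats::quantile(x, c(alpha / 2, 1 - alpha / 2), names = FALSE)
}

#' Confidence-interval-inversion p-value
#'
#' The p-value for the two-sided point null `theta = theta0` is the smallest
#' `alpha` in `[1/B, 1]` such that `theta0` lies outside the `1 - alpha`
#' percentile interval of the bootstrap distribution. A degenerate
#' distribution equal to `theta0` gives p = 1; complete separation gives the
#' floor `1/B`.
#'
#' @param theta bootstrap draws of the statistic (length B).
#' @param theta0 null value (default 0).
#' @return p-value in `[1/B, 1]`.
#' @export
ci_inversion_pvalue <- function(theta, theta0 = 0) {
  B <- length(theta)
  alphas <- seq_len(B) / B
  lo <- stats::quantile(theta, alphas / 2, names = FALSE)
  hi <- stats::quantile(theta, 1 - alphas / 2, names = FALSE)
  outside <- theta0 < lo | theta0 > hi
  if (!any(outside)) return(1)
  max(1 / B, alphas[which(outside)[1L]])
}

#' Bootstrap comparison of embeddings
#'
#' Scores each embedding on `B` bootstrap resamples of the cells (the same
#' resampled indices applied to every method per replicate), re-clustering
#' each resample at the resolution found on the full data (merging down to
#' the target cluster count when needed). Reports per-method score
#' distributions with percentile CIs, and pairwise CI-inversion p-values on
#' score differences with Benjamini-Hochberg adjustment.
#'
#' The score is the overall benchmark score when `batches` is supplied,
#' otherwise the biological-conservation mean.
#'
#' @param embeddings named list of cells x d matrices over the same cells.
#' @param cell_types ground-truth labels.
#' @param batches optional per-cell batch labels.
#' @param B bootstrap replicates (default 1000; must satisfy `B >= 2/alpha`).
#' @param alpha 1 - confidence level (default 0.05).
#' @param K neighbors for graphs (default 20).
#' @param resolutions resolution grid for the full-data search.
#' @param seed RNG seed (resampling and clustering).
#' @return object of class `bootstrap_result`: per-method `scores` (B draws),
#'   `point` (full-data score), `ci`, and a `comparisons` data.frame with
#'   `p_value` and `p_adjusted`.
#' @export
bootstrap_compare <- function(embeddings, cell_types, batches = NULL,
                              B = 1000L, alpha = 0.05, K = 20L,
                              resolutions = seq(0.1, 2, by = 0.1),
                              seed = 1L) {
  if (is.null(names(embeddings)) || any(!nzchar(names(embeddings))))
    stop("embeddings must be a named list")
  n <- length(cell_types)
  for (e in embeddings)
    if (nrow(e) != n) stop("all embeddings must share the same cell universe")
  if (B < 2 / alpha)
    stop("B too small for alpha = ", alpha, " (need B >= ", ceiling(2 / alpha), ")")
  target_k <- length(unique(cell_types))

  score_one <- function(emb, idx, resolution) {
    emb <- emb[idx, , drop = FALSE]
    ct <- cell_types[idx]
    g <- build_graphs(emb, K = min(K, nrow(emb) - 1L))
    labels <- cluster_cells(g, resolution = resolution, seed = seed)
    if (length(unique(labels)) > target_k)
      labels <- merge_small_clusters(labels, g$snn, target_k = target_k)
    bio <- bio_conservation(emb, labels, ct)
    if (is.null(batches)) return(bio$mean)
    bc <- batch_correction_scores(emb, batches[idx], ct, labels, K = K,
                                  seed = seed)
    overall_score(bio$mean, min(1, max(0, bc$mean)))
  }

  res_full <- lapply(embeddings, function(emb) {
    g <- build_graphs(emb, K = min(K, n - 1L))
    resolution_search(g, target_k, resolutions, seed = seed)
  })
  point <- vapply(names(embeddings), function(m) {
    score_one(embeddings[[m]], seq_len(n), res_full[[m]]$resolution)
  }, numeric(1L))

  idx_mat <- with_seed(seed, {
    matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  })
  scores <- matrix(NA_real_, B, length(embeddings),
                   dimnames = list(NULL, names(embeddings)))
  for (b in seq_len(B)) {
    idx <- idx_mat[, b]
    if (length(unique(cell_types[idx])) < 2L) idx <- seq_len(n)  # degenerate resample
    for (m in names(embeddings))
      scores[b, m] <- score_one(embeddings[[m]], idx, res_full[[m]]$resolution)
  }

  cis <- lapply(names(embeddings), function(m) percentile_ci(scores[, m], alpha))
  names(cis) <- names(embeddings)

  pairs <- utils::combn(names(embeddings), 2L, simplify = FALSE)
  comparisons <- NULL
  if (length(pairs)) {
    comparisons <- do.call(rbind, lapply(pairs, function(pr) {
      theta <- scores[, pr[1L]] - scores[, pr[2L]]
      data.frame(method_a = pr[1L], method_b = pr[2L],
                 delta = mean(theta),
                 p_value = ci_inversion_pvalue(theta, 0),
                 stringsAsFactors = FALSE)
    }))
    comparisons$p_adjusted <- stats::p.adjust(comparisons$p_value, method = "BH")
  }
  structure(list(B = B, alpha = alpha, point = point, scores = scores,
                 ci = cis, comparisons = comparisons,
                 resolution = vapply(res_full, `[[`, numeric(1L), "resolution")),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: B=%d, alpha=%g\n", x$B, x$alpha))
  for (m in names(x$point))
    cat(sprintf("  %s: %.4f [%.4f, %.4f]\n", m, x$point[[m]],
                x$ci[[m]][1L], x$ci[[m]][2L]))
  if (!is.null(x$comparisons)) {
    cat("pairwise comparisons:\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Full benchmark report for one embedding
#'
#' Convenience wrapper: resolution search to the number of cell types,
#' biological conservation, batch correction (when batches are given) and
#' the weighted overall score.
#'
#' @param embedding cells x d matrix.
#' @param cell_types ground-truth labels.
#' @param batches optional batch labels.
#' @param K neighbors (default 20).
#' @param resolutions resolution grid.
#' @param seed clustering seed.
#' @return list of class `score_report`: `bio`, `batch` (or NULL), `overall`,
#'   `labels`, `resolution`.
#' @export
score_embedding <- function(embedding, cell_types, batches = NULL, K = 20L,
                            resolutions = seq(0.1, 2, by = 0.1), seed = 0L) {
  g <- build_graphs(embedding, K = min(K, nrow(embedding) - 1L))
  rs <- resolution_search(g, length(unique(cell_types)), resolutions,
                          seed = seed)
  bio <- bio_conservation(embedding, rs$labels, cell_types)
  batch <- NULL
  overall <- bio$mean
  if (!is.null(batches)) {
    batch <- batch_correction_scores(embedding, batches, cell_types,
                                     rs$labels, K = K, seed = seed)
    overall <- overall_score(bio$mean, min(1, max(0, batch$mean)))
  }
  structure(list(bio = bio, batch = batch, overall = overall,
                 labels = rs$labels, resolution = rs$resolution,
                 K = K),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("score_report: bio=%.4f", x$bio$mean))
  if (!is.null(x$batch)) cat(sprintf(", batch=%.4f", x$batch$mean))
  cat(sprintf(", overall=%.4f (resolution %.2f)\n", x$overall, x$resolution))
  invisible(x)
}
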