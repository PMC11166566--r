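## small trained model shared by downstream tests
dm_model <- local({
  sim <- small_sim(n_cells = 50, n_events = 80, seed = 12)
  suppressMessages(train_embedding(sim$dataset, small_cfg(epochs = 2L)))
})

test_that("motif consensus takes the per-column argmax with A<C<G<T ties", {
  pwm <- cbind(c(1, 0, 0, 0), c(0, 0, 1, 0))
  rownames(pwm) <- c("A", "C", "G", "T")
  expect_identical(motif_consensus(pwm), "AG")
  expect_identical(motif_consensus(matrix(0.25, 4, 1,
                                          dimnames = list(c("A","C","G","T")))), "A")
  m <- motif_model("toy", matrix(c(0.7, 0.1, 0.1, 0.1), 4, 7,
                                 dimnames = list(c("A","C","G","T"))))
  expect_error(motif_consensus(m, min_width = 8), "below the required")
})

test_that("motif embeddings use the constituent k-mers and are strand-invariant", {
  k <- dm_model$spec$k
  # width k: the single k-mer's own embedding row
  km <- "ACGTAC"
  expect_identical(
    embed_motif(km, dm_model),
    dm_model$feature_embeddings[canonical_kmer_index(km, k) + 1L, ]
  )
  # consensus and its reverse complement embed identically
  cons <- "ACGTTGCCA"
  expect_identical(embed_motif(cons, dm_model),
                   embed_motif(revcomp(cons), dm_model))
  # width k+2: exactly (w1 + w2 + w3) / 3^P
  s <- "ACGTACGT"
  idx <- kmer_bag(s, dm_model$spec)
  manual <- colSums(dm_model$feature_embeddings[sort(idx) + 1L, ]) / 3^0.5
  expect_equal(embed_motif(s, dm_model), manual)
  expect_error(embed_motif("ACGT", dm_model), "shorter than k")
})

test_that("TF activity scores are per-motif z-scores over cells", {
  mot <- motif_model("toy", matrix(c(.97,.01,.01,.01), 4, 8,
                                   dimnames = list(c("A","C","G","T"))))
  ts <- tf_activity_scores(dm_model, list(mot))
  expect_identical(dim(ts$scores), c(50L, 1L))
  expect_lt(abs(mean(ts$scores[, 1])), 1e-8)
  n <- nrow(ts$scores)
  sd_pop <- stats::sd(ts$scores[, 1]) * sqrt((n - 1) / n)
  expect_lt(abs(sd_pop - 1), 1e-6)
  # two cells: z-scores are +1 / -1 under population SD
  two <- dm_model
  two$cell_embeddings <- dm_model$cell_embeddings[1:2, ]
  two$cell_ids <- dm_model$cell_ids[1:2]
  ts2 <- tf_activity_scores(two, list(mot))
  expect_equal(sort(as.numeric(ts2$scores)), c(-1, 1))
  # constant raw column is flagged and zeroed
  dup <- dm_model
  dup$cell_embeddings <- dm_model$cell_embeddings[rep(1, 5), ]
  dup$cell_ids <- paste0("c", 1:5)
  expect_warning(ts3 <- tf_activity_scores(dup, list(mot)), "constant")
  expect_true(all(ts3$scores == 0))
})

test_that("KNN and SNN graphs follow the contracts", {
  # 3 points on a line, K = 1: middle point is both ends' neighbor
  emb <- cbind(c(0, 1, 2.1), c(0, 0, 0)) + matrix(rnorm(6, sd = 1e-8), 3)
  g <- build_graphs(emb, K = 1, metric = "euclidean")
  expect_identical(g$knn[1, 1], 2L)
  expect_identical(g$knn[3, 1], 2L)

  # identical duplicate cells share an identical neighborhood: SNN weight 1
  set.seed(3)
  emb2 <- matrix(rnorm(20 * 4), 20, 4)
  emb2[2, ] <- emb2[1, ]
  g2 <- build_graphs(emb2, K = 3)
  expect_equal(g2$snn[1, 2], 1)
  # symmetry
  expect_identical(g2$snn, Matrix::t(g2$snn))
  expect_error(build_graphs(emb2, K = 20), "K must be smaller")
})

test_that("exact KNN matches a naive double-loop oracle", {
  set.seed(8)
  emb <- matrix(rnorm(500 * 8), 500, 8)
  K <- 10
  g <- build_graphs(emb, K = K)
  norm <- emb / sqrt(rowSums(emb^2))
  D <- 1 - tcrossprod(norm)
  recall <- vapply(seq_len(500), function(i) {
    truth <- setdiff(order(D[i, ]), i)[seq_len(K)]
    length(intersect(truth, g$knn[i, ])) / K
  }, numeric(1))
  expect_gte(mean(recall), 0.95)   # ties may permute the boundary
  expect_gt(mean(recall), 0.999)   # exact search: essentially 1
})

test_that("Louvain clustering separates disconnected cliques deterministically", {
  set.seed(4)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = .05), n), 2, center, "+")
  emb <- rbind(blob(c(0, 0), 30), blob(c(20, 0), 30))
  g <- build_graphs(emb, K = 10, metric = "euclidean")
  lab <- cluster_cells(g, resolution = 0.8, seed = 1)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:30])), 1L)
  # resolution -> 0 on a connected graph: one cluster
  g1 <- build_graphs(blob(c(0, 0), 40), K = 10, metric = "euclidean")
  expect_identical(length(unique(cluster_cells(g1, resolution = 1e-4, seed = 1))), 1L)
  # determinism
  expect_identical(cluster_cells(g, 0.8, seed = 7), cluster_cells(g, 0.8, seed = 7))
})

test_that("small clusters merge into their most connected larger neighbor", {
  # block SNN: clusters A (1:5), B (6:10), singleton 11 connected only to A
  n <- 11
  w <- matrix(0, n, n)
  w[1:5, 1:5] <- 0.8; w[6:10, 6:10] <- 0.8
  w[11, 1:5] <- 0.5; w[1:5, 11] <- 0.5
  diag(w) <- 0
  snn <- methods::as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix")
  labels <- c(rep(1, 5), rep(2, 5), 3)
  merged <- merge_small_clusters(labels, snn, min_size = 2)
  expect_identical(length(unique(merged)), 2L)
  expect_identical(merged[11], merged[1])
  # no cluster below min_size: identity
  expect_identical(merge_small_clusters(labels, snn, min_size = 1),
                   as.integer(factor(labels)))
  # target_k drives merges; cluster count never increases
  m2 <- merge_small_clusters(labels, snn, target_k = 2)
  expect_identical(length(unique(m2)), 2L)

  # 4 planted blocks, target 3: smallest merges into its adjacent block
  w4 <- matrix(0, 14, 14)
  blocks <- list(1:4, 5:8, 9:12, 13:14)
  for (b in blocks) w4[b, b] <- 0.9
  w4[13:14, 9:12] <- 0.4; w4[9:12, 13:14] <- 0.4   # block 4 adjacent to 3
  diag(w4) <- 0
  lab4 <- rep(1:4, c(4, 4, 4, 2))
  m4 <- merge_small_clusters(lab4, methods::as(Matrix::Matrix(w4, sparse = TRUE), "CsparseMatrix"),
                             target_k = 3)
  expect_identical(length(unique(m4)), 3L)
  expect_identical(m4[13], m4[9])
})

test_that("joint cell/TF tables stack typed rows with cosine distances", {
  t0 <- joint_cell_tf_table(dm_model, list())
  expect_identical(nrow(t0$embedding), nrow(dm_model$cell_embeddings))
  mot <- motif_model("toy", matrix(c(.97,.01,.01,.01), 4, 8,
                                   dimnames = list(c("A","C","G","T"))))
  t1 <- joint_cell_tf_table(dm_model, list(mot))
  expect_identical(nrow(t1$embedding), nrow(dm_model$cell_embeddings) + 1L)
  expect_identical(t1$type, c(rep("cell", 50), "motif"))
  # a motif identical to a cell vector sits at distance 0 from it
  fake <- dm_model
  fake$cell_embeddings[7, ] <- embed_motif(mot, dm_model)
  t2 <- joint_cell_tf_table(fake, list(mot))
  D <- as.matrix(t2$distance)
  expect_lt(D[7, 51], 1e-12)
})
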