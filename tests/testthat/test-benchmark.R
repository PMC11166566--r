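test_that("clustering metrics match brute-force oracles on 200-cell instances", {
  set.seed(51)
  n <- 200
  emb <- matrix(rnorm(n * 5), n, 5)
  a <- sample(letters[1:4], n, replace = TRUE)
  b <- sample(letters[1:3], n, replace = TRUE)

  expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-10)
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-10)
  expect_equal(homogeneity(a, b), oracle_homogeneity(a, b), tolerance = 1e-10)

  D <- as.matrix(stats::dist(emb))
  expect_equal(silhouette_widths(emb, a), oracle_silhouette(D, a),
               tolerance = 1e-10)

  # independent library cross-checks
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
  }
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(as.integer(factor(a)), dist(emb))
    expect_equal(sort(silhouette_widths(emb, a)), sort(sil[, "sil_width"]),
                 tolerance = 1e-10)
  }
})

test_that("graph connectivity and kBET acceptance match naive implementations", {
  set.seed(52)
  emb <- rbind(matrix(rnorm(60 * 3), 60, 3),
               matrix(rnorm(60 * 3, mean = 8), 60, 3))
  types <- rep(c("t1", "t2"), each = 60)
  batches <- rep(rep(c("b1", "b2"), 30), 2)
  clusters <- types

  bc <- suppressWarnings(
    batch_correction_scores(emb, batches, types, clusters, K = 10,
                            max_tested = 1000)
  )
  gc_oracle <- mean(c(oracle_lcc_fraction(emb[types == "t1", ], 10),
                      oracle_lcc_fraction(emb[types == "t2", ], 10)))
  expect_equal(bc$graph_connectivity, gc_oracle, tolerance = 1e-10)

  # kBET oracle: same neighborhoods (cosine), same chi-squared rule
  nk <- max(5, min(50, floor(mean(table(batches)) / 2)))
  kb_oracle <- mean(vapply(c("t1", "t2"), function(t) {
    idx <- which(types == t)
    e <- emb[idx, ]; bt <- batches[idx]
    props <- table(bt) / length(bt)
    norm <- e / sqrt(rowSums(e^2))
    Dm <- 1 - tcrossprod(norm)
    diag(Dm) <- -1
    acc <- vapply(seq_along(idx), function(i) {
      nb <- order(Dm[i, ])[seq_len(min(nk, length(idx) - 1))]
      counts <- table(factor(bt[nb], levels = names(props)))
      oracle_kbet_accept(as.numeric(counts), as.numeric(props))
    }, numeric(1))
    mean(acc)
  }, numeric(1)))
  expect_equal(bc$kbet_acceptance, kb_oracle, tolerance = 1e-10)
})

test_that("bio conservation behaves at the reference points", {
  set.seed(53)
  # perfect agreement: NMI = ARI = homogeneity = 1
  blob <- function(center, n, sd = 1) sweep(matrix(rnorm(n * 4, sd = sd), n), 2, center, "+")
  emb <- rbind(blob(c(0,0,0,0), 50), blob(c(30,0,0,0), 50))
  types <- rep(c("t1", "t2"), each = 50)
  bio <- bio_conservation(emb, types, types)
  expect_equal(bio$nmi, 1)
  expect_equal(bio$ari, 1)
  expect_equal(bio$homogeneity, 1)
  # two blobs separated by 10+ sigma: ASW rescaled above 0.9
  expect_gt(bio$asw, 0.9)
  expect_equal(bio$mean, mean(c(bio$asw, 1, 1, 1)))

  # random labels on balanced types: |ARI| below 0.05
  n <- 1000
  t2 <- rep(c("a", "b"), n / 2)
  r <- sample(c("a", "b"), n, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(t2, r)), 0.05)

  expect_error(bio_conservation(emb, types, rep("one", 100)), "single cell type")
})

test_that("batch metrics behave at the reference points", {
  set.seed(54)
  # single batch over all cells: mixing metrics are 1 by convention
  emb <- matrix(rnorm(80 * 4), 80, 4)
  types <- rep(c("t1", "t2"), each = 40)
  bc1 <- batch_correction_scores(emb, rep("b1", 80), types, types)
  expect_equal(bc1$batch_nmi, 1)
  expect_equal(bc1$kbet_acceptance, 1)
  expect_equal(bc1$batch_asw, 1)

  # perfectly interleaved batches in one homogeneous cloud: kBET accepts
  n <- 2000
  emb2 <- matrix(rnorm(n * 6), n, 6)
  batches <- rep(c("b1", "b2"), n / 2)
  bc2 <- batch_correction_scores(emb2, batches, rep("t", n), rep(1, n),
                                 K = 15, max_tested = 400)
  expect_gte(bc2$kbet_acceptance, 0.9)
  expect_equal(bc2$batch_nmi, 1, tolerance = 0.05)

  # batches fully separated into two blobs of one type along distinct
  # directions (cosine neighborhoods): kBET rejects everywhere
  emb3 <- rbind(cbind(rnorm(100, 50), rnorm(100), rnorm(100)),
                cbind(rnorm(100), rnorm(100, 50), rnorm(100)))
  b3 <- rep(c("b1", "b2"), each = 100)
  bc3 <- batch_correction_scores(emb3, b3, rep("t", 200), rep(1, 200), K = 10)
  expect_lt(bc3$kbet_acceptance, 0.05)
  expect_lt(bc3$batch_asw, 0.5)

  # a cell type present in a single batch is excluded with a warning
  types4 <- rep(c("t1", "t2"), each = 100)
  b4 <- c(rep("b1", 100), rep(c("b1", "b2"), 50))
  expect_warning(batch_correction_scores(matrix(rnorm(200 * 3), 200), b4,
                                         types4, types4),
                 "single batch")
})

test_that("the overall score is the stated weighted average", {
  expect_identical(overall_score(1, 0), 0.6)
  expect_identical(overall_score(0, 1), 0.4)
  for (x in c(0, 0.3, 1)) expect_equal(overall_score(x, x), x)
  expect_error(overall_score(1.2, 0))
})

test_that("resolution search hits the target cluster count", {
  set.seed(55)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, sd = .1), n), 2, center, "+")
  emb <- rbind(blob(c(0, 0), 30), blob(c(10, 0), 30), blob(c(0, 10), 30))
  g <- build_graphs(emb, K = 10, metric = "euclidean")
  rs <- resolution_search(g, 3)
  expect_identical(length(unique(rs$labels)), 3L)
  expect_false(rs$merged)
  expect_identical(rs$resolution, 0.1)  # cliques split at the lowest grid value

  # overshooting candidates are reduced by merging
  rs2 <- resolution_search(g, 2)
  expect_identical(length(unique(rs2$labels)), 2L)
  expect_true(rs2$merged)

  # when every candidate undershoots the target, the search errors with guidance
  g1 <- build_graphs(blob(c(0, 0), 40), K = 10, metric = "euclidean")
  expect_error(resolution_search(g1, 2, resolutions = c(1e-6)), "finer or higher")
})

test_that("percentile CIs and CI-inversion p-values are calibrated", {
  # method against itself: degenerate difference distribution, p = 1
  expect_identical(ci_inversion_pvalue(rep(0, 500)), 1)
  # complete separation: the 1/B floor
  expect_identical(ci_inversion_pvalue(rnorm(400, mean = 50)), 1 / 400)
  # interval endpoints are the stated quantiles
  x <- rnorm(1000)
  expect_identical(percentile_ci(x, 0.1),
                   unname(stats::quantile(x, c(0.05, 0.95))))

  # BH adjustment is monotone on sorted p-values, never below raw, capped at 1
  p <- sort(runif(20))
  adj <- stats::p.adjust(p, "BH")
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("bootstrap comparison shares resamples and floors p-values", {
  set.seed(56)
  blob <- function(center, n) sweep(matrix(rnorm(n * 3, sd = .3), n), 2, center, "+")
  emb <- rbind(blob(c(0, 0, 0), 40), blob(c(6, 0, 0), 40))
  types <- rep(c("t1", "t2"), each = 40)
  noisy <- emb + matrix(rnorm(length(emb), sd = 2.5), nrow(emb))
  res <- bootstrap_compare(list(clean = emb, clean2 = emb, noisy = noisy),
                           types, B = 40, alpha = 0.1, K = 10, seed = 3)
  expect_identical(dim(res$scores), c(40L, 3L))
  # identical methods: identical scores in every replicate, p = 1
  expect_identical(res$scores[, "clean"], res$scores[, "clean2"])
  cmp <- res$comparisons
  self_row <- cmp$method_a == "clean" & cmp$method_b == "clean2"
  expect_identical(cmp$p_value[self_row], 1)
  expect_true(all(cmp$p_adjusted >= cmp$p_value))
  expect_gte(res$point[["clean"]], res$point[["noisy"]])
  expect_error(bootstrap_compare(list(a = emb, b = noisy), types, B = 10,
                                 alpha = 0.05, K = 10),
               "B too small")
})
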