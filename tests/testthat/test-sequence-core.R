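test_that("canonical k-mer indexing collapses strand pairs", {
  expect_identical(canonical_kmer_index("A", 1), canonical_kmer_index("T", 1))
  expect_identical(canonical_kmer_index("C", 1), canonical_kmer_index("G", 1))
  expect_false(canonical_kmer_index("A", 1) == canonical_kmer_index("C", 1))

  # palindrome maps to a single row equal to its own revcomp's
  expect_identical(canonical_kmer_index("ACGTACGT"),
                   canonical_kmer_index(revcomp("ACGTACGT")))

  # all 16 dimers collapse to exactly 10 canonical classes
  dimers <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1,
                  paste, collapse = "")
  expect_identical(length(unique(canonical_kmer_index(dimers, 2))), 10L)

  # ambiguous bases give the skip sentinel, never an index
  expect_true(is.na(canonical_kmer_index("ANGT", 4)))
})

test_that("canonical index is bijective on canonical k-mers (k <= 6)", {
  for (k in 1:6) {
    n <- if (k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
    idx <- seq_len(n) - 1L
    kmers <- decode_kmer_index(idx, k)
    expect_identical(canonical_kmer_index(kmers, k), as.integer(idx))
    # every k-mer and its revcomp share an index in the dense range
    all_kmers <- do.call(paste0, expand.grid(rep(list(c("A","C","G","T")), k)))
    i1 <- canonical_kmer_index(all_kmers, k)
    i2 <- canonical_kmer_index(revcomp(all_kmers), k)
    expect_identical(i1, i2)
    expect_true(all(i1 >= 0 & i1 < n))
    expect_identical(length(unique(i1)), as.integer(n))
  }
})

test_that("k-mer bags slide one base at a time and skip ambiguous windows", {
  spec <- feature_spec()
  s <- random_dna_seq(150)
  expect_length(kmer_bag(s, spec), 150 - 8 + 1)

  spec4 <- feature_spec(k = 4, N = 1, bucket = 0)
  expect_length(kmer_bag("ACGNACGT", spec4), 1L)
  expect_identical(kmer_bag("ACGNACGT", spec4),
                   canonical_kmer_index("ACGT", 4))

  expect_error(kmer_bag("ACG", spec4), "shorter than k")

  # multiset equality with the reverse complement
  s2 <- random_dna_seq(40)
  expect_identical(sort(kmer_bag(s2, spec4)),
                   sort(kmer_bag(revcomp(s2), spec4)))
})

test_that("pair context features follow the window/pair combinatorics", {
  spec <- feature_spec(k = 4, N = 3, bucket = 1000)
  kmers <- c("ACGT", "CGTA", "GTAC")
  expect_length(ngram_pair_features(kmers, spec), 3L)  # one window, 3 pairs

  # m retained k-mers vs brute-force window enumeration, m = 3..6
  for (m in 3:6) {
    km <- substring(random_dna_seq(m + 3), 1:m, 4:(m + 3))
    expect_length(ngram_pair_features(km, spec),
                  length(oracle_ngram_pairs(km, 3)))
  }
  # fewer than N k-mers: no full window, no features
  expect_length(ngram_pair_features(kmers[1:2], spec), 0L)
  expect_length(ngram_pair_features(kmers, feature_spec(k = 4, N = 1, bucket = 0)), 0L)
})

test_that("pair hash is strand-symmetric and lands in the bucket range", {
  spec <- feature_spec(k = 5, N = 3, bucket = 997)
  for (i in 1:20) {
    s <- random_dna_seq(30)
    b1 <- feature_bag(s, spec)
    b2 <- feature_bag(revcomp(s), spec)
    expect_identical(sort(b1$ngram_indices), sort(b2$ngram_indices))
    expect_true(all(b1$ngram_indices >= spec$kmer_rows))
    expect_true(all(b1$ngram_indices < spec$kmer_rows + spec$bucket))
  }
})

test_that("induced embeddings follow sum(w)/M^P", {
  fm <- matrix(rnorm(50 * 4), 50, 4)
  # M = 1: the feature's own vector, any P
  expect_equal(induced_embedding(7, fm, P = 0.9), fm[8, ])
  # 4 identical vectors at P = 0.5: 4w / 2 = 2w
  fm4 <- rbind(fm[1, ], fm[1, ], fm[1, ], fm[1, ])
  expect_equal(induced_embedding(c(0, 1, 2, 3), fm4, P = 0.5), 2 * fm[1, ])
  # P = 0 plain sum; P = 1 plain mean
  rows <- c(2, 5, 9, 9)
  expect_equal(induced_embedding(rows, fm, P = 0), colSums(fm[rows + 1, ]))
  expect_equal(induced_embedding(rows, fm, P = 1), colMeans(fm[rows + 1, ]))
  expect_error(induced_embedding(numeric(0), fm), "no embeddable features")
})

test_that("induced embeddings are exactly strand-invariant for N in {1,3,5}", {
  set.seed(11)
  fm <- matrix(rnorm(3000 * 6), 3000, 6)
  for (N in c(1L, 3L, 5L)) {
    spec <- feature_spec(k = 5, N = N, bucket = if (N > 1) 2000 else 0)
    for (i in 1:40) {
      s <- random_dna_seq(sample(20:80, 1))
      e1 <- induced_embedding(feature_bag(s, spec), fm, spec$P)
      e2 <- induced_embedding(feature_bag(revcomp(s), spec), fm, spec$P)
      expect_identical(e1, e2)
    }
  }
})

test_that("R and compiled featurizers agree bit for bit", {
  for (i in 1:25) {
    k <- sample(2:8, 1); N <- sample(1:4, 1)
    bucket <- if (N > 1) sample(c(100, 999, 50000), 1) else 0
    spec <- feature_spec(k = k, N = N, bucket = bucket)
    s <- random_dna_seq(sample(c(10, 50, 200), 1))
    if (i %% 5 == 0) substr(s, 4, 4) <- "N"
    b <- feature_bag(s, spec)
    cf <- seqspace:::cpp_featurize(s, k, N, bucket)
    expect_identical(as.integer(b$kmer_indices), as.integer(cf$kmer_indices))
    expect_identical(as.numeric(b$ngram_indices), as.numeric(cf$ngram_indices))
  }
})

test_that("feature spec validates its invariants", {
  expect_error(feature_spec(k = 0), "k must be")
  expect_error(feature_spec(k = 13), "k must be")
  expect_error(feature_spec(N = 0), "N must be")
  expect_error(feature_spec(N = 3, bucket = 0), "bucket may be 0 only")
  expect_silent(feature_spec(N = 1, bucket = 0))
  # canonical row counts: even and odd k
  expect_identical(feature_spec(k = 8)$kmer_rows, as.integer((4^8 + 4^4) / 2))
  expect_identical(feature_spec(k = 5, N = 1, bucket = 0)$kmer_rows,
                   as.integer(4^5 / 2))
})
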