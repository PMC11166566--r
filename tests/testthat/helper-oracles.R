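## Independent brute-force oracles used across the suite. These are written
## as direct transcriptions (loops, textbook formulas), deliberately separate
## from the package implementations they check.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## direct transcription of the margin ranking loss equation
oracle_loss <- function(lhs, pos, negs, margin) {
  cosim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  K <- nrow(negs)
  total <- 0
  for (k in seq_len(K)) {
    total <- total + max(0, margin - cosim(lhs, pos) + cosim(lhs, negs[k, ]))
  }
  total / K
}

## enumerate pair features of m k-mers with window N by explicit loops
oracle_ngram_pairs <- function(kmers, N) {
  m <- length(kmers)
  out <- list()
  if (m < N) return(out)
  for (w in seq_len(m - N + 1)) {
    win <- kmers[w:(w + N - 1)]
    for (a in seq_len(N - 1)) {
      for (b in (a + 1):N) {
        out[[length(out) + 1]] <- c(win[a], win[b])
      }
    }
  }
  out
}

## silhouette by double loop
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- Inf
    for (l in unique(labels[!own])) {
      b <- min(b, mean(D[i, labels == l]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

## NMI with arithmetic normalization, from explicit probability tables
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  H <- function(x) {
    h <- 0
    for (u in unique(x)) { p <- mean(x == u); h <- h - p * log(p) }
    h
  }
  ha <- H(a); hb <- H(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in ua) for (j in ub) {
    pij <- sum(a == i & b == j) / n
    if (pij > 0) mi <- mi + pij * log(pij / (mean(a == i) * mean(b == j)))
  }
  mi / ((ha + hb) / 2)
}

oracle_ari <- function(a, b) {
  n <- length(a)
  pairs_same <- function(x, i, j) x[i] == x[j]
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- pairs_same(a, i, j); sb <- pairs_same(b, i, j)
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == exp_idx) return(1)
  (n11 - exp_idx) / (max_idx - exp_idx)
}

oracle_homogeneity <- function(classes, clusters) {
  n <- length(classes)
  H <- function(x) {
    h <- 0
    for (u in unique(x)) { p <- mean(x == u); h <- h - p * log(p) }
    h
  }
  hc <- H(classes)
  if (hc == 0) return(1)
  hck <- 0
  for (k in unique(clusters)) {
    idx <- clusters == k
    pk <- mean(idx)
    for (c in unique(classes[idx])) {
      pck <- mean(classes[idx] == c)
      hck <- hck - pk * pck * log(pck)
    }
  }
  1 - hck / hc
}

## largest connected component of a KNN graph by breadth-first search
oracle_lcc_fraction <- function(emb, K) {
  n <- nrow(emb)
  if (n == 1) return(1)
  K <- min(K, n - 1)
  norm <- emb / sqrt(rowSums(emb^2))
  D <- 1 - tcrossprod(norm)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- setdiff(order(D[i, ]), i)[seq_len(K)]
  }
  # undirected: symmetrize
  for (i in seq_len(n)) for (j in adj[[i]]) {
    if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
  }
  seen <- rep(FALSE, n)
  best <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    best <- max(best, size)
  }
  best / n
}

## chi-squared goodness-of-fit acceptance for one neighborhood
oracle_kbet_accept <- function(counts, props, alpha = 0.05) {
  expected <- sum(counts) * props
  x2 <- sum((counts - expected)^2 / expected)
  p <- stats::pchisq(x2, df = length(counts) - 1, lower.tail = FALSE)
  as.numeric(p >= alpha)
}

## tiny deterministic synthetic dataset for fast trainer tests
small_sim <- function(n_cells = 60, n_types = 3, n_events = 120, seed = 5) {
  simulate_dataset(n_cells = n_cells, n_types = n_types, n_events = n_events,
                   event_len = 300L, motif_insert_rate = 0.9, dropout = 0.3,
                   seed = seed)
}

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(epochs = 3L, seed = 42L,
         spec = feature_spec(k = 6L, N = 2L, bucket = 5000)),
    list(...)
  )
  do.call(training_config, args)
}
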