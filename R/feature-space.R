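## sequence_core: canonical k-mer indexing, k-mer bags, hashed k-mer-pair
## (N-gram) context features, and induced entity embeddings.

.kmer_cache <- new.env(parent = emptyenv())

## Canonical k-mer machinery for one k, cached. A k-mer and its reverse
## complement share one dense 0-based row index; the canonical representative
## is the lexicographic (== numeric base-4) minimum of the pair.
kmer_index_table <- function(k) {
  key <- as.character(k)
  if (!is.null(.kmer_cache[[key]])) return(.kmer_cache[[key]])
  stopifnot(k >= 1L, k <= 12L)
  codes <- seq_len(4^k) - 1
  rc <- rc_code(codes, k)
  canon <- pmin(codes, rc)
  is_canon <- codes <= rc
  cum <- cumsum(is_canon)
  lut <- as.integer(cum[canon + 1] - 1)  # code -> dense 0-based index
  tab <- list(
    k = k,
    lut = lut,
    n_canonical = as.integer(cum[length(cum)]),
    canon_codes = codes[is_canon]
  )
  .kmer_cache[[key]] <- tab
  tab
}

## Number of canonical k-mer rows: (4^k + 4^(k/2))/2 for even k, 4^k/2 odd.
n_kmer_rows <- function(k) {
  if (k %% 2L == 0L) as.integer((4^k + 4^(k / 2)) / 2) else as.integer(4^k / 2)
}

#' Feature space specification
#'
#' Defines the k-mer / context-feature universe used to featurize DNA
#' sequences: k-mer length `k`, context window `N` (in k-mers), the number of
#' hash rows (`bucket`) reserved for k-mer-pair context features, and the
#' entity-embedding normalization exponent `P`. Each k-mer shares an embedding
#' row with its reverse complement, so there are `(4^k + 4^(k/2))/2` (even k)
#' or `4^k/2` (odd k) k-mer rows, followed by `bucket` hashed rows.
#'
#' @param k k-mer length in bp (1..12; default 8).
#' @param N context window size in consecutive k-mers (default 3). `N = 1`
#'   disables pair features.
#' @param bucket number of hash rows for k-mer-pair features (default
#'   2,000,000 when `N > 1`, else 0). Must be positive when `N > 1`.
#' @param P normalization exponent for induced entity embeddings (default
#'   0.5): an entity of `M` features is embedded as `sum(w_i) / M^P`.
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(k = 8L, N = 3L, bucket = if (N > 1L) 2e6 else 0, P = 0.5) {
  k <- as.integer(k); N <- as.integer(N); bucket <- as.numeric(bucket)
  if (is.na(k) || k < 1L || k > 12L)
    stop("k must be an integer in 1..12")
  if (is.na(N) || N < 1L) stop("N must be >= 1")
  if (bucket < 0) stop("bucket must be >= 0")
  if (bucket == 0 && N > 1L) stop("bucket may be 0 only when N = 1")
  if (!is.finite(P)) stop("P must be a finite real")
  structure(
    list(k = k, N = N, bucket = bucket, P = P, kmer_rows = n_kmer_rows(k)),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf(
    "feature_spec: k=%d (%d canonical k-mer rows), N=%d, bucket=%s, P=%g\n",
    x$k, x$kmer_rows, x$N, format(x$bucket, big.mark = ","), x$P
  ))
  invisible(x)
}

#' Canonical k-mer row index
#'
#' Maps a k-mer to its dense 0-based embedding-row index; a k-mer and its
#' reverse complement map to the same index. K-mers containing any ambiguous
#' base return `NA` (the "skip" sentinel), never an index.
#'
#' @param kmer character vector of k-mers (all the same length).
#' @param k k-mer length; defaults to `nchar` of the first element.
#' @return integer vector of 0-based indices, `NA` where ambiguous.
#' @export
canonical_kmer_index <- function(kmer, k = nchar(kmer[[1L]])) {
  if (any(nchar(kmer) != k)) stop("all k-mers must have length k")
  tab <- kmer_index_table(k)
  codes <- vapply(kmer, function(s) {
    cs <- seq_codes(s)
    if (anyNA(cs)) NA_real_ else sum(cs * 4^((k - 1):0))
  }, numeric(1L), USE.NAMES = FALSE)
  out <- rep(NA_integer_, length(codes))
  ok <- !is.na(codes)
  out[ok] <- tab$lut[codes[ok] + 1]
  out
}

#' Decode a canonical k-mer row index
#'
#' Inverse of [canonical_kmer_index()]: returns the canonical (lexicographic
#' minimum of the strand pair) k-mer string for a dense row index.
#'
#' @param index integer vector of 0-based canonical row indices.
#' @param k k-mer length.
#' @return character vector of canonical k-mers.
#' @export
decode_kmer_index <- function(index, k) {
  tab <- kmer_index_table(k)
  if (any(index < 0 | index >= tab$n_canonical))
    stop("index out of range for k = ", k)
  code_to_kmer(tab$canon_codes[index + 1L], k)
}

#' Bag of canonical k-mers for a sequence
#'
#' Slides a k bp window along the sequence one nucleotide at a time and
#' returns the ordered canonical row indices of the retained windows. Windows
#' containing an ambiguous base (anything other than A/C/G/T) are skipped;
#' the order of retained windows is preserved. A clean length-L sequence
#' yields L - k + 1 indices.
#'
#' @param sequence a single DNA string, length >= k.
#' @param spec a [feature_spec()].
#' @return integer vector of 0-based canonical k-mer row indices.
#' @export
kmer_bag <- function(sequence, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  if (nchar(sequence) < spec$k)
    stop("sequence shorter than k (", spec$k, ")")
  codes <- window_codes(seq_codes(sequence), spec$k)
  codes <- codes[!is.na(codes)]
  tab <- kmer_index_table(spec$k)
  tab$lut[codes + 1]
}

## Strand-symmetric hash of an ordered k-mer pair (codes c1, c2):
## the canonical representative of {(c1,c2), (rc(c2),rc(c1))} is the numeric
## minimum of the two concatenated 2k-mer codes; hashed modulo bucket with
## exact modular double arithmetic (valid for k <= 12, bucket <= ~4e6).
ngram_pair_hash <- function(c1, c2, k, bucket) {
  r1 <- rc_code(c1, k)
  r2 <- rc_code(c2, k)
  swap <- (r2 < c1) | (r2 == c1 & r1 < c2)
  h1 <- ifelse(swap, r2, c1)
  h2 <- ifelse(swap, r1, c2)
  ((h1 %% bucket) * (4^k %% bucket) + h2) %% bucket
}

#' Hashed k-mer-pair context features
#'
#' For every window of `N` consecutive retained k-mers, every pair of k-mers
#' within the window becomes one context feature, hashed into
#' `[kmer_rows, kmer_rows + bucket)`. The hash is strand-symmetric
#' (`h(a, b) == h(revcomp(b), revcomp(a))`), so full-sequence feature bags are
#' invariant to reverse complementation as multisets. Only full windows of
#' `N` k-mers generate pairs; duplicate pairs from overlapping windows are
#' kept as repeated features.
#'
#' @param kmers character vector of retained k-mers in sequence order (as
#'   returned by sliding a window over the sequence and dropping ambiguous
#'   windows).
#' @param spec a [feature_spec()] with `N >= 2` and `bucket > 0`.
#' @return numeric vector of 0-based global row indices (already offset by
#'   the k-mer row count); empty when `N = 1` or fewer than `N` k-mers.
#' @export
ngram_pair_features <- function(kmers, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  if (spec$N == 1L) return(numeric(0))
  if (spec$bucket <= 0) stop("bucket must be > 0 when N > 1")
  m <- length(kmers)
  if (m < spec$N) return(numeric(0))
  k <- spec$k
  codes <- vapply(kmers, function(s) {
    cs <- seq_codes(s)
    if (anyNA(cs)) stop("ambiguous base in retained k-mer: ", s)
    sum(cs * 4^((k - 1):0))
  }, numeric(1L), USE.NAMES = FALSE)
  pairs1 <- integer(0); pairs2 <- integer(0)
  within <- utils::combn(spec$N, 2L)
  for (w in seq_len(m - spec$N + 1L)) {
    pairs1 <- c(pairs1, w - 1L + within[1L, ])
    pairs2 <- c(pairs2, w - 1L + within[2L, ])
  }
  h <- ngram_pair_hash(codes[pairs1], codes[pairs2], k, spec$bucket)
  spec$kmer_rows + h
}

#' Featurize a DNA sequence
#'
#' Full feature bag of a sequence: ordered canonical k-mer indices plus
#' hashed k-mer-pair context features. This is the entity representation used
#' for training examples and induced embeddings.
#'
#' @param sequence a single DNA string.
#' @param spec a [feature_spec()].
#' @return an object of class `feature_bag`: list with `kmer_indices`
#'   (0-based canonical rows, ordered), `ngram_indices` (0-based global rows,
#'   offset by the k-mer row count) and `M` (total feature count).
#' @export
feature_bag <- function(sequence, spec = feature_spec()) {
  stopifnot(inherits(spec, "feature_spec"))
  if (nchar(sequence) < spec$k)
    stop("sequence shorter than k (", spec$k, ")")
  codes <- window_codes(seq_codes(sequence), spec$k)
  codes <- codes[!is.na(codes)]
  tab <- kmer_index_table(spec$k)
  kmer_idx <- tab$lut[codes + 1]
  ngram_idx <- numeric(0)
  if (spec$N > 1L && length(codes) >= spec$N) {
    within <- utils::combn(spec$N, 2L)
    m <- length(codes)
    pairs1 <- integer(0); pairs2 <- integer(0)
    for (w in seq_len(m - spec$N + 1L)) {
      pairs1 <- c(pairs1, w - 1L + within[1L, ])
      pairs2 <- c(pairs2, w - 1L + within[2L, ])
    }
    h <- ngram_pair_hash(codes[pairs1], codes[pairs2], spec$k, spec$bucket)
    ngram_idx <- spec$kmer_rows + h
  }
  structure(
    list(kmer_indices = kmer_idx, ngram_indices = ngram_idx,
         M = length(kmer_idx) + length(ngram_idx)),
    class = "feature_bag"
  )
}

#' Induced entity embedding from a feature bag
#'
#' An entity composed of `M` features with embedding rows `w_1..w_M` is
#' embedded as `sum(w_i) / M^P`. Rows are summed in sorted index order so the
#' result is bit-identical for any reordering of the same multiset of
#' features (in particular for a sequence and its reverse complement).
#'
#' @param bag a `feature_bag`, or a numeric vector of 0-based global feature
#'   row indices.
#' @param feature_matrix features x d embedding matrix.
#' @param P normalization exponent.
#' @return numeric d-vector.
#' @export
induced_embedding <- function(bag, feature_matrix, P = 0.5) {
  rows <- if (inherits(bag, "feature_bag")) {
    c(bag$kmer_indices, bag$ngram_indices)
  } else {
    as.numeric(bag)
  }
  if (length(rows) == 0L) stop("no embeddable features")
  rows <- sort(rows) + 1
  if (max(rows) > nrow(feature_matrix))
    stop("feature index out of range of feature_matrix")
  colSums(feature_matrix[rows, , drop = FALSE]) / length(rows)^P
}

#' Embed a DNA sequence with a trained model
#'
#' Featurizes the sequence under the model's feature spec and returns its
#' induced embedding in the shared cell/k-mer space.
#'
#' @param model a trained `seqspace_model`.
#' @param sequence a single DNA string.
#' @return numeric d-vector.
#' @export
embed_sequence <- function(model, sequence) {
  stopifnot(inherits(model, "seqspace_model"))
  bag <- feature_bag(sequence, model$spec)
  if (bag$M == 0L) stop("no embeddable features")
  induced_embedding(bag, model$feature_embeddings, model$spec$P)
}
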