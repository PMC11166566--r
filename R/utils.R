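## Shared low-level helpers: DNA codes, reverse complements, cosine similarity.

DNA_BASES <- c("A", "C", "G", "T")

.base_code_lut <- local({
  v <- rep(NA_integer_, 256)
  v[utf8ToInt("A") + 1L] <- 0L
  v[utf8ToInt("C") + 1L] <- 1L
  v[utf8ToInt("G") + 1L] <- 2L
  v[utf8ToInt("T") + 1L] <- 3L
  v
})

#' Reverse complement of DNA strings
#'
#' Vectorized over `x`. Ambiguous IUPAC codes other than A/C/G/T are
#' complemented positionally where defined (N stays N); case is preserved
#' for A/C/G/T.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## Integer base-4 codes (A=0, C=1, G=2, T=3) for each character of one
## sequence; NA for anything not A/C/G/T (after uppercasing).
seq_codes <- function(s) {
  .base_code_lut[utf8ToInt(toupper(s)) + 1L]
}

## Codes of all k-length windows of a sequence, as doubles (exact to 2^53).
## Windows containing an ambiguous base get NA. Returns numeric(0) when the
## sequence is shorter than k.
window_codes <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0))
  pow <- 4^((k - 1L):0L)
  idx <- outer(seq_len(n) - 1L, seq_len(k) - 1L, "+") + 1L
  m <- matrix(codes[idx], nrow = n)
  out <- as.numeric(m %*% pow)
  out[rowSums(is.na(m)) > 0L] <- NA_real_
  out
}

## Reverse-complement code of k-mer codes (vectorized, exact doubles).
rc_code <- function(code, k) {
  rc <- numeric(length(code))
  c0 <- code
  for (j in seq_len(k)) {
    digit <- c0 %% 4
    c0 <- (c0 - digit) / 4
    rc <- rc * 4 + (3 - digit)
  }
  rc
}

## Decode k-mer codes back to strings (vectorized).
code_to_kmer <- function(code, k) {
  n <- length(code)
  if (n == 0L) return(character(0))
  chars <- vector("list", k)
  c0 <- code
  for (j in k:1) {
    digit <- c0 %% 4
    c0 <- (c0 - digit) / 4
    chars[[j]] <- DNA_BASES[digit + 1L]
  }
  do.call(paste0, chars)
}

#' Cosine similarity
#'
#' Cosine similarity between vectors, or row-wise between two matrices.
#' A zero-norm vector has similarity 0 to everything (convention used
#' throughout the package to avoid NaN with freshly initialized rows).
#'
#' @param a,b numeric vectors, or matrices with vectors in rows.
#' @return a scalar (vector input) or an `nrow(a) x nrow(b)` matrix.
#' @export
cosine_similarity <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    a <- rbind(a); b <- rbind(b)
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    s <- tcrossprod(a, b)
    s <- s / outer(na, nb)
    s[!is.finite(s)] <- 0
    return(s)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

## L2-normalize matrix rows; zero rows stay zero.
l2_normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

## Coerce anything matrix-like to a numeric dgCMatrix.
as_dgc <- function(m) {
  m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(m, "generalMatrix")
  m <- methods::as(m, "dMatrix")
  methods::as(m, "CsparseMatrix")
}

## Run an expression with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
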