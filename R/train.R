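## trainer: training configuration, streamed example generation (delegated to
## the compiled core), margin ranking loss, and variable-event selection.

#' Training configuration
#'
#' Defaults follow the method's stated defaults: latent dimension `d = 30`,
#' sampled sequence length `L = 150` bp, 20 training examples per event per
#' epoch, 50 epochs, and a feature spec with `k = 8`, `N = 3`, `P = 0.5`.
#' `K_neg`, `margin` and `lr0` default to the StarSpace-style values 10,
#' 0.05 and 0.01.
#'
#' @param d latent dimension (>= 2).
#' @param L sampled sequence length in bp (>= `spec$k`). Events shorter than
#'   `L` are used whole.
#' @param epochs number of passes over the event set.
#' @param examples_per_event training examples generated per event per epoch.
#' @param K_neg negative cells sampled per example.
#' @param margin hinge margin of the ranking loss.
#' @param lr0 initial learning rate (decays linearly to 0 over training).
#' @param batch_aware if `TRUE`, negative cells are drawn from the positive
#'   cell's batch, so training never separates batches.
#' @param seed integer seed for the trainer RNG (initialization and all
#'   sampling); runs with the same seed are bit-reproducible.
#' @param threads reserved; only 1 (deterministic single-threaded training)
#'   is supported.
#' @param optimizer `"sgd"` (plain steps with the linearly decaying rate, the
#'   StarSpace behaviour; default) or `"adagrad"` (per-row adaptive scaling
#'   of the same decaying rate).
#' @param spec a [feature_spec()].
#' @return an object of class `training_config`.
#' @export
training_config <- function(d = 30L, L = 150L, epochs = 50L,
                            examples_per_event = 20L, K_neg = 10L,
                            margin = 0.05, lr0 = 0.01, batch_aware = FALSE,
                            seed = 1L, threads = 1L,
                            optimizer = c("sgd", "adagrad"),
                            spec = feature_spec()) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(spec, "feature_spec"))
  d <- as.integer(d); L <- as.integer(L); epochs <- as.integer(epochs)
  if (d < 2L) stop("d must be >= 2")
  if (L < spec$k) stop("L must be >= k")
  if (epochs < 0L) stop("epochs must be >= 0")
  if (examples_per_event < 1L) stop("examples_per_event must be >= 1")
  if (K_neg < 1L) stop("K_neg must be >= 1")
  if (margin <= 0) stop("margin must be > 0")
  if (lr0 <= 0) stop("lr0 must be > 0")
  if (threads != 1L) stop("only threads = 1 (deterministic) is supported")
  structure(
    list(d = d, L = L, epochs = epochs,
         examples_per_event = as.integer(examples_per_event),
         K_neg = as.integer(K_neg), margin = margin, lr0 = lr0,
         similarity = "cosine", batch_aware = isTRUE(batch_aware),
         seed = as.integer(seed), threads = 1L, optimizer = optimizer,
         spec = spec),
    class = "training_config"
  )
}

#' @export
print.training_config <- function(x, ...) {
  cat(sprintf(
    paste0("training_config: d=%d, L=%d, epochs=%d, %d examples/event, ",
           "K_neg=%d, margin=%g, lr0=%g, batch_aware=%s, seed=%d\n"),
    x$d, x$L, x$epochs, x$examples_per_event, x$K_neg, x$margin, x$lr0,
    x$batch_aware, x$seed
  ))
  print(x$spec)
  invisible(x)
}

#' Assemble one scATAC-seq dataset for training
#'
#' Bundles a binary cell-by-event matrix with the event DNA sequences and
#' optional per-cell batch labels. Counts are binarized; event sequences are
#' matched to matrix columns by name when both are named.
#'
#' @param matrix cells x events matrix (sparse or dense); any positive entry
#'   is treated as accessible.
#' @param sequences named character vector of event DNA sequences (one per
#'   event column).
#' @param cell_ids optional cell identifiers (default: matrix rownames or
#'   generated).
#' @param batch optional per-cell batch labels.
#' @param dataset_id dataset label used for multi-dataset co-embedding.
#' @return an object of class `event_dataset`.
#' @export
event_dataset <- function(matrix, sequences, cell_ids = NULL, batch = NULL,
                          dataset_id = "dataset1") {
  m <- as_dgc(matrix)
  m@x <- as.numeric(m@x > 0)
  m <- Matrix::drop0(m)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(m)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%04d", seq_len(nrow(m)))
  }
  if (length(cell_ids) != nrow(m))
    stop("cell_ids length does not match matrix rows")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  ev_names <- colnames(m)
  if (is.null(ev_names)) ev_names <- sprintf("event_%05d", seq_len(ncol(m)))
  sequences <- as.character(sequences)
  if (!is.null(names(sequences)) && !is.null(colnames(m))) {
    missing <- setdiff(ev_names, names(sequences))
    if (length(missing))
      stop("sequences missing for events: ", paste(utils::head(missing, 3), collapse = ", "))
    sequences <- sequences[ev_names]
  } else if (length(sequences) != ncol(m)) {
    stop("sequences length does not match matrix columns")
  }
  if (!is.null(batch)) {
    if (length(batch) != nrow(m)) stop("batch length does not match cells")
    batch <- as.character(batch)
  }
  rownames(m) <- cell_ids
  colnames(m) <- ev_names
  structure(
    list(matrix = m, sequences = stats::setNames(toupper(sequences), ev_names),
         cell_ids = cell_ids, batch = batch, dataset_id = dataset_id),
    class = "event_dataset"
  )
}

#' Collect one or more datasets for co-embedding
#'
#' @param ... `event_dataset` objects (or a single list of them). Dataset ids
#'   must be unique; cell ids are made globally unique by prefixing the
#'   dataset id when they collide.
#' @return an object of class `dataset_collection`.
#' @export
dataset_collection <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1L]], "event_dataset")) ds <- ds[[1L]]
  if (!length(ds)) stop("at least one dataset required")
  for (d in ds) stopifnot(inherits(d, "event_dataset"))
  ids <- vapply(ds, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("dataset_id values must be unique")
  all_cells <- unlist(lapply(ds, `[[`, "cell_ids"))
  if (anyDuplicated(all_cells)) {
    ds <- lapply(ds, function(d) {
      d$cell_ids <- paste(d$dataset_id, d$cell_ids, sep = ":")
      rownames(d$matrix) <- d$cell_ids
      d
    })
  }
  structure(list(datasets = ds), class = "dataset_collection")
}

## Canonical strand orientation for an event sequence: the lexicographic
## minimum of {sequence, reverse complement}. Makes training exactly
## strand-invariant (identical RNG stream, identical feature bags).
canonical_orientation <- function(sequences) {
  up <- toupper(sequences)
  rc <- revcomp(up)
  out <- ifelse(rc < up, rc, up)
  names(out) <- names(sequences)
  out
}

#' Margin ranking loss
#'
#' `Loss = (1/K) * sum_k max(0, margin - sim(lhs, pos) + sim(lhs, neg_k))`
#' with cosine similarity (zero-norm vectors have similarity 0). The
#' per-negative hinge values are attached as attribute `"hinges"`; only
#' negatives with a positive hinge receive gradient updates during training.
#'
#' @param lhs_emb,pos_emb numeric d-vectors.
#' @param neg_embs numeric matrix with one negative embedding per row (a
#'   single vector is treated as one negative).
#' @param margin hinge margin.
#' @return the scalar loss, with attribute `hinges`.
#' @export
margin_ranking_loss <- function(lhs_emb, pos_emb, neg_embs, margin = 0.05) {
  if (!is.matrix(neg_embs)) neg_embs <- matrix(neg_embs, nrow = 1L)
  stopifnot(length(lhs_emb) == length(pos_emb),
            ncol(neg_embs) == length(lhs_emb))
  sp <- cosine_similarity(lhs_emb, pos_emb)
  sn <- as.numeric(cosine_similarity(matrix(lhs_emb, nrow = 1L), neg_embs))
  hinges <- pmax(0, margin - sp + sn)
  structure(mean(hinges), hinges = hinges)
}

#' Sample one training example
#'
#' Reference (R-level) implementation of the per-example sampling contract,
#' mirroring the compiled trainer: an L bp subsequence uniform over the event
#' (the whole sequence when shorter than L), a positive cell uniform over the
#' cells with the event accessible, and `K_neg` negatives uniform without
#' replacement over cells lacking the event within the positive's dataset
#' (and batch, when `batch_aware`). Returns `NULL` (an skipped example) when
#' no eligible negative exists.
#'
#' @param event event column index (1-based).
#' @param dataset an `event_dataset`.
#' @param cfg a [training_config()].
#' @return a list with `sequence`, `bag`, `positive`, `negatives`, or `NULL`.
#' @export
sample_training_example <- function(event, dataset, cfg = training_config()) {
  stopifnot(inherits(dataset, "event_dataset"))
  col <- dataset$matrix[, event]
  positives <- which(col > 0)
  if (!length(positives)) stop("event has no positive cell")
  s <- canonical_orientation(dataset$sequences[[event]])
  len <- nchar(s)
  if (len >= cfg$L) {
    off <- if (len == cfg$L) 0L else sample.int(len - cfg$L + 1L, 1L) - 1L
    s <- substr(s, off + 1L, off + cfg$L)
  }
  pos <- positives[sample.int(length(positives), 1L)]
  eligible <- which(col == 0)
  if (cfg$batch_aware && !is.null(dataset$batch)) {
    eligible <- eligible[dataset$batch[eligible] == dataset$batch[pos]]
  }
  if (!length(eligible)) return(NULL)
  negs <- if (length(eligible) <= cfg$K_neg) eligible
          else eligible[sample.int(length(eligible), cfg$K_neg)]
  list(sequence = s, bag = feature_bag(s, cfg$spec), positive = pos,
       negatives = negs, dataset_id = dataset$dataset_id)
}

#' One SGD step on a training example
#'
#' Applies a single margin-ranking-loss update to small embedding matrices:
#' gradients flow to the feature rows of the left-hand-side bag (scaled by
#' `1/M^P`), the positive cell row, and negative cell rows with a positive
#' hinge; zero-hinge negatives are untouched. Per-row Adagrad-style scaling.
#' Intended for inspection and testing; [train_embedding()] runs the same
#' update in compiled code.
#'
#' @param cell_embeddings cells x d matrix.
#' @param feature_embeddings features x d matrix.
#' @param feature_rows 0-based global feature row indices (with multiplicity).
#' @param positive 1-based positive cell row.
#' @param negatives 1-based negative cell rows.
#' @param margin,P,lr loss margin, normalization exponent, learning rate.
#' @param acc_cell,acc_feat per-row Adagrad accumulators (default zeros).
#' @return list with updated matrices, `loss`, `hinges` and accumulators.
#' @export
sgd_step <- function(cell_embeddings, feature_embeddings, feature_rows,
                     positive, negatives, margin = 0.05, P = 0.5, lr = 0.01,
                     acc_cell = NULL, acc_feat = NULL) {
  if (is.null(acc_cell)) acc_cell <- numeric(nrow(cell_embeddings))
  if (is.null(acc_feat)) acc_feat <- numeric(nrow(feature_embeddings))
  res <- cpp_sgd_step(cell_embeddings, feature_embeddings,
                      as.numeric(feature_rows), as.integer(positive) - 1L,
                      as.integer(negatives) - 1L, margin, P, lr,
                      acc_cell, acc_feat)
  if (!all(is.finite(res$cell_embeddings)) || !all(is.finite(res$feature_embeddings)))
    stop("non-finite values after SGD update")
  res
}

#' Train the cell / k-mer co-embedding
#'
#' Streams training examples (a sampled event subsequence as the left-hand
#' side, one positive cell as the right-hand side, `K_neg` negative cells)
#' and minimizes the cosine margin ranking loss by SGD with per-row
#' Adagrad-style steps and a linearly decaying base rate. Per epoch,
#' `examples_per_event x usable events` examples are generated in random
#' order across all datasets; the event, positive and negatives of an example
#' always come from the same dataset (and the same batch when
#' `cfg$batch_aware`). Events with no positive cell, no negative cell, or a
#' sequence shorter than `k` are excluded. With a fixed `cfg$seed` the run is
#' bit-reproducible.
#'
#' @param datasets an `event_dataset`, a `dataset_collection`, or a list of
#'   `event_dataset`s.
#' @param cfg a [training_config()].
#' @return an object of class `seqspace_model`: `cell_embeddings` (cells x d,
#'   rownames = cell ids), `feature_embeddings` ((kmer_rows + bucket) x d),
#'   `spec`, `config`, per-cell `dataset` and `batch`, `loss_trace` (mean
#'   loss per epoch) and diagnostic counters.
#' @export
train_embedding <- function(datasets, cfg = training_config()) {
  if (inherits(datasets, "event_dataset")) datasets <- dataset_collection(datasets)
  if (!inherits(datasets, "dataset_collection")) datasets <- dataset_collection(datasets)
  ds <- datasets$datasets
  n_by_ds <- vapply(ds, function(d) nrow(d$matrix), integer(1L))
  offsets <- cumsum(c(0L, n_by_ds[-length(n_by_ds)]))
  n_cells <- sum(n_by_ds)
  cell_ids <- unlist(lapply(ds, `[[`, "cell_ids"), use.names = FALSE)
  cell_ds <- rep(vapply(ds, `[[`, "", "dataset_id"), n_by_ds)
  cell_batch <- unlist(lapply(ds, function(d) {
    if (is.null(d$batch)) rep("batch1", nrow(d$matrix)) else d$batch
  }), use.names = FALSE)

  group_key <- if (cfg$batch_aware) paste(cell_ds, cell_batch, sep = "\r")
               else cell_ds
  group_id <- as.integer(factor(group_key, levels = unique(group_key))) - 1L
  group_cells <- lapply(sort(unique(group_id)), function(g) which(group_id == g) - 1L)

  event_seq <- character(0)
  event_pos <- list()
  for (i in seq_along(ds)) {
    d <- ds[[i]]
    cs <- Matrix::colSums(d$matrix)
    usable <- which(cs > 0 & cs < nrow(d$matrix) & nchar(d$sequences) >= cfg$spec$k)
    if (!length(usable))
      stop("dataset '", d$dataset_id, "' has no usable events")
    if (length(usable) < ncol(d$matrix))
      message(sprintf("dataset '%s': %d/%d events excluded (all-0/all-1 or too short)",
                      d$dataset_id, ncol(d$matrix) - length(usable), ncol(d$matrix)))
    m <- methods::as(d$matrix, "CsparseMatrix")
    for (e in usable) {
      p <- m@i[(m@p[e] + 1L):m@p[e + 1L]]  # 0-based rows, already sorted
      event_pos[[length(event_pos) + 1L]] <- p + offsets[i]
    }
    event_seq <- c(event_seq, canonical_orientation(d$sequences[usable]))
  }

  res <- cpp_train(unname(event_seq), event_pos, group_id, group_cells,
                   n_cells, cfg$d, cfg$spec$k, cfg$spec$N, cfg$spec$bucket,
                   cfg$L, cfg$epochs, cfg$examples_per_event, cfg$K_neg,
                   cfg$margin, cfg$lr0, cfg$spec$P, as.numeric(cfg$seed),
                   identical(cfg$optimizer, "adagrad"))
  if (!all(is.finite(res$cell_embeddings)))
    stop("non-finite cell embeddings after training")
  rownames(res$cell_embeddings) <- cell_ids
  structure(
    list(cell_embeddings = res$cell_embeddings,
         feature_embeddings = res$feature_embeddings,
         spec = cfg$spec, config = cfg, cell_ids = cell_ids,
         dataset = cell_ds, batch = cell_batch,
         loss_trace = res$loss_trace,
         examples_skipped = res$examples_skipped,
         zero_norm_pairs = res$zero_norm_pairs,
         n_usable_events = res$n_usable_events),
    class = "seqspace_model"
  )
}

#' @export
print.seqspace_model <- function(x, ...) {
  cat(sprintf(
    "seqspace_model: %d cells x %d dims; %d feature rows (%d k-mer + %s bucket)\n",
    nrow(x$cell_embeddings), ncol(x$cell_embeddings),
    nrow(x$feature_embeddings), x$spec$kmer_rows,
    format(x$spec$bucket, big.mark = ",")
  ))
  if (length(x$loss_trace))
    cat(sprintf("  final epoch mean loss: %.5f (%d epochs)\n",
                utils::tail(x$loss_trace, 1L), length(x$loss_trace)))
  invisible(x)
}

#' Select variable events by TF-IDF + truncated SVD
#'
#' Ranks events by their loading variance on the top singular components of
#' the TF-IDF-transformed binary matrix, excluding the component most
#' correlated with per-cell depth (which tracks coverage rather than
#' biology). Events with no variation across cells (all-0 or all-1 columns)
#' rank last. A lightweight variable-feature selector, not a reimplementation
#' of any specific LSI pipeline.
#'
#' @param matrix cells x events binary matrix.
#' @param n_top number of events to keep.
#' @param n_components rank of the truncated SVD (default 10).
#' @return integer vector of event column indices, most variable first.
#' @export
select_variable_events <- function(matrix, n_top, n_components = 10L) {
  m <- as_dgc(matrix)
  m@x <- as.numeric(m@x > 0)
  n_events <- ncol(m)
  if (n_top > n_events) {
    warning("n_top > number of events; returning all events")
    n_top <- n_events
  }
  depth <- Matrix::rowSums(m)
  depth[depth == 0] <- 1
  cs <- Matrix::colSums(m)
  degenerate <- cs == 0 | cs == nrow(m)
  idf <- log(1 + nrow(m) / pmax(cs, 1))
  tf <- m / depth
  x <- as.matrix(tf) %*% Matrix::Diagonal(n_events, idf)
  x <- as.matrix(x)
  s <- min(n_components, nrow(x) - 1L, n_events - 1L)
  sv <- svd(scale(x, center = TRUE, scale = FALSE), nu = s, nv = s)
  dcor <- abs(apply(sv$u, 2L, function(u) suppressWarnings(stats::cor(u, log1p(depth)))))
  dcor[is.na(dcor)] <- 0
  keep <- setdiff(seq_len(s), which.max(dcor))
  score <- rowSums((sv$v[, keep, drop = FALSE] %*%
                      diag(sv$d[keep], length(keep)))^2)
  score[degenerate] <- -Inf
  order(score, decreasing = TRUE)[seq_len(n_top)]
}
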