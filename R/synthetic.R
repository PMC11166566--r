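## synthetic: self-contained scATAC-like datasets with known cell types,
## planted motifs, and optional batch effects.

## Fixed 10-bp planted consensus sequences (pairwise dissimilar on both
## strands); extended with random draws when more types are requested.
.planted_consensus <- c("TTGACTCATC", "GACCACGTGG", "CAGATAAGGC",
                        "CCATTGTTCT", "GGGAGGAGCC")

planted_motif_pwm <- function(consensus, mutation_rate = 0.05) {
  w <- nchar(consensus)
  pwm <- matrix(mutation_rate / 3, 4L, w, dimnames = list(DNA_BASES, NULL))
  bases <- strsplit(consensus, "")[[1L]]
  for (j in seq_len(w)) pwm[bases[j], j] <- 1 - mutation_rate
  pwm
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1L))
}

mutate_consensus <- function(consensus, rate) {
  bases <- strsplit(consensus, "")[[1L]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    for (j in which(hit)) bases[j] <- sample(setdiff(DNA_BASES, bases[j]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate an scATAC-like dataset with planted structure
#'
#' Generates a binary cell-by-event matrix, event DNA sequences and full
#' ground truth. Background sequences are i.i.d. uniform A/C/G/T. Event roles:
#' half the events are type-specific (split equally across types), 20% are
#' shared, 10% are batch-artifact events when `n_batches > 1`, the rest are
#' background. Each type-specific event carries its type's 10-bp consensus
#' (with per-position mutation rate 0.05) inserted at a uniform position with
#' probability `motif_insert_rate`. Accessibility: a type-specific event is
#' open in its own type's cells with probability `1 - dropout` and elsewhere
#' with 0.02; shared events are open with 0.3 everywhere; background events
#' with 0.05; a batch-artifact event favors one batch with probability
#' `plogis(qlogis(0.1) + batch_strength)` versus 0.1. A fraction of events is
#' short (below the default 150 bp sampling length) to exercise the
#' short-event rule. Regeneration from the same arguments and seed is
#' bit-identical.
#'
#' @param n_cells number of cells (>= 10 per type).
#' @param n_types number of cell types.
#' @param n_events number of events.
#' @param event_len event sequence length in bp.
#' @param motif_insert_rate per-event insertion probability for type-specific
#'   events.
#' @param dropout accessibility dropout for type-specific events in their own
#'   type.
#' @param n_batches number of batches (1 = no batch structure).
#' @param batch_strength log-odds shift of batch-artifact events toward their
#'   favored batch (0 = none).
#' @param short_event_frac fraction of events shorter than the sampling
#'   length (default 0.05).
#' @param short_event_len length of short events (default 100 bp).
#' @param mutation_rate per-position mutation rate of inserted consensus
#'   copies (default 0.05).
#' @param seed RNG seed.
#' @return list with `dataset` (an [event_dataset()]) and `truth` (class
#'   `synthetic_truth`): `cell_types`, `batch`, `motifs` (per-type
#'   `motif_model`s), `consensus`, `event_roles`, `event_type`,
#'   `favored_batch`, `inserted` (logical per event), `config`, `seed`.
#' @export
simulate_dataset <- function(n_cells = 300L, n_types = 3L, n_events = 1000L,
                             event_len = 500L, motif_insert_rate = 0.9,
                             dropout = 0.5, n_batches = 1L,
                             batch_strength = 0, short_event_frac = 0.05,
                             short_event_len = 100L, mutation_rate = 0.05,
                             seed = 1L) {
  if (n_cells < 10L * n_types) stop("need at least 10 cells per type")
  if (n_events < 10L * n_types) stop("need at least 10 events per type")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  with_seed(seed, {
    cell_types <- sample(rep_len(seq_len(n_types), n_cells))
    batch <- sample(rep_len(seq_len(n_batches), n_cells))

    consensus <- .planted_consensus
    while (length(consensus) < n_types)
      consensus <- c(consensus, random_dna(1L, 10L))
    consensus <- consensus[seq_len(n_types)]
    motifs <- lapply(seq_len(n_types), function(t) {
      motif_model(sprintf("planted_type%d", t),
                  planted_motif_pwm(consensus[t], mutation_rate),
                  source = "synthetic")
    })

    n_specific <- floor(0.5 * n_events)
    n_shared <- floor(0.2 * n_events)
    n_artifact <- if (n_batches > 1L) floor(0.1 * n_events) else 0L
    roles <- c(rep("specific", n_specific), rep("shared", n_shared),
               rep("artifact", n_artifact),
               rep("background", n_events - n_specific - n_shared - n_artifact))
    roles <- sample(roles)
    event_type <- rep(NA_integer_, n_events)
    event_type[roles == "specific"] <-
      rep_len(seq_len(n_types), sum(roles == "specific"))
    favored_batch <- rep(NA_integer_, n_events)
    favored_batch[roles == "artifact"] <-
      rep_len(seq_len(n_batches), sum(roles == "artifact"))

    lens <- rep(event_len, n_events)
    short <- sample(n_events, round(short_event_frac * n_events))
    lens[short] <- short_event_len

    sequences <- character(n_events)
    inserted <- logical(n_events)
    for (e in seq_len(n_events)) {
      s <- random_dna(1L, lens[e])
      if (roles[e] == "specific" && stats::runif(1L) < motif_insert_rate) {
        ins <- mutate_consensus(consensus[event_type[e]], mutation_rate)
        pos <- sample.int(lens[e] - nchar(ins) + 1L, 1L)
        substr(s, pos, pos + nchar(ins) - 1L) <- ins
        inserted[e] <- TRUE
      }
      sequences[e] <- s
    }
    names(sequences) <- sprintf("event_%05d", seq_len(n_events))

    p_art_hi <- stats::plogis(stats::qlogis(0.1) + batch_strength)
    prob <- matrix(0, n_cells, n_events)
    for (e in seq_len(n_events)) {
      prob[, e] <- switch(
        roles[e],
        specific = ifelse(cell_types == event_type[e], 1 - dropout, 0.02),
        shared = 0.3,
        artifact = ifelse(batch == favored_batch[e], p_art_hi, 0.1),
        background = 0.05
      )
    }
    x <- matrix(stats::rbinom(n_cells * n_events, 1L, prob), n_cells, n_events)
    rownames(x) <- sprintf("cell_%04d", seq_len(n_cells))
    colnames(x) <- names(sequences)

    dataset <- event_dataset(x, sequences,
                             batch = sprintf("batch%d", batch),
                             dataset_id = "synthetic")
    truth <- structure(
      list(cell_types = sprintf("type%d", cell_types),
           batch = sprintf("batch%d", batch),
           motifs = motifs, consensus = consensus,
           event_roles = roles, event_type = event_type,
           favored_batch = favored_batch, inserted = inserted,
           event_lengths = lens,
           config = list(n_cells = n_cells, n_types = n_types,
                         n_events = n_events, event_len = event_len,
                         motif_insert_rate = motif_insert_rate,
                         dropout = dropout, n_batches = n_batches,
                         batch_strength = batch_strength,
                         short_event_frac = short_event_frac,
                         short_event_len = short_event_len,
                         mutation_rate = mutation_rate),
           seed = seed),
      class = "synthetic_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Frozen small benchmark configuration
#'
#' The fixed synthetic benchmark used across the test suite: 300 cells,
#' 3 types, 1000 events of 500 bp, insert rate 0.9, dropout 0.5, 2 batches,
#' seed 7. `batch_strength` selects the no-batch-effect (0) or
#' batch-confounded (3) variant.
#'
#' @param batch_strength 0 or 3 (any non-negative value accepted).
#' @return named list of [simulate_dataset()] arguments.
#' @export
default_benchmark_config <- function(batch_strength = 0) {
  list(n_cells = 300L, n_types = 3L, n_events = 1000L, event_len = 500L,
       motif_insert_rate = 0.9, dropout = 0.5, n_batches = 2L,
       batch_strength = batch_strength, seed = 7L)
}

#' Generate the frozen benchmark dataset
#'
#' @param batch_strength passed to [default_benchmark_config()].
#' @param ... overrides forwarded to [simulate_dataset()].
#' @return see [simulate_dataset()].
#' @export
simulate_benchmark <- function(batch_strength = 0, ...) {
  args <- utils::modifyList(default_benchmark_config(batch_strength),
                            list(...))
  do.call(simulate_dataset, args)
}
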