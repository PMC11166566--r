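## io_formats: Matrix Market triplets with sidecars, BED intervals, FASTA
## sequence extraction, JASPAR / MEME motif parsing, model serialization.

#' Read a cell-by-event matrix from Matrix Market triplets
#'
#' Reads a sparse matrix plus one-column sidecar files of cell barcodes and
#' event names, binarizes counts (any value > 0 becomes 1) and auto-detects
#' orientation from the sidecar lengths (a transposed events x cells matrix
#' is flipped). Events with all-0 or all-1 columns are flagged in attribute
#' `"degenerate_events"`; they are excluded later, before training.
#'
#' @param mtx_path Matrix Market coordinate file.
#' @param cells_path text file, one cell barcode per line (first column if
#'   tab-separated).
#' @param events_path text file, one event name per line.
#' @param batch_path optional text file of per-cell batch labels (aligned
#'   with `cells_path`), or a two-column TSV of barcode and batch.
#' @return a cells x events binary `dgCMatrix` with dimnames, attributes
#'   `batch` and `degenerate_events`.
#' @export
read_cell_event_matrix <- function(mtx_path, cells_path, events_path,
                                   batch_path = NULL) {
  m <- as_dgc(Matrix::readMM(mtx_path))
  cells <- read_sidecar(cells_path)
  events <- read_sidecar(events_path)
  if (nrow(m) == length(cells) && ncol(m) == length(events)) {
    # cells x events as stored
  } else if (nrow(m) == length(events) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else if (nrow(m) != length(cells)) {
    stop(sprintf("matrix dimensions %dx%d match neither sidecar: '%s' has %d entries",
                 nrow(m), ncol(m), cells_path, length(cells)))
  } else {
    stop(sprintf("matrix dimensions %dx%d match neither sidecar: '%s' has %d entries",
                 nrow(m), ncol(m), events_path, length(events)))
  }
  m <- as_dgc(m)
  m@x <- as.numeric(m@x > 0)
  m <- Matrix::drop0(m)
  dimnames(m) <- list(cells, events)
  cs <- Matrix::colSums(m)
  degenerate <- events[cs == 0 | cs == nrow(m)]
  if (length(degenerate))
    message(length(degenerate), " event(s) with all-0 or all-1 columns flagged")
  batch <- NULL
  if (!is.null(batch_path)) {
    bt <- utils::read.table(batch_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(bt) >= 2L) {
      batch <- bt[[2L]][match(cells, bt[[1L]])]
      if (anyNA(batch)) stop("batch file '", batch_path, "' is missing barcodes")
    } else {
      if (nrow(bt) != length(cells))
        stop("batch file '", batch_path, "' has ", nrow(bt),
             " rows but there are ", length(cells), " cells")
      batch <- bt[[1L]]
    }
  }
  attr(m, "degenerate_events") <- degenerate
  attr(m, "batch") <- batch
  m
}

read_sidecar <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty sidecar file: ", path)
  vapply(strsplit(x, "\t", fixed = TRUE), `[[`, "", 1L)
}

#' Read genomic intervals from a BED file
#'
#' BED3+ with 0-based half-open coordinates (kept as the internal
#' convention). The 4th column, when present, provides event names; otherwise
#' names are `chrom:start-end`.
#'
#' @param path BED file.
#' @return a data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]),
                    end = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  out$name <- if (ncol(df) >= 4L) as.character(df[[4L]])
              else sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  if (any(out$start >= out$end)) stop("BED intervals must have start < end")
  if (anyDuplicated(out$name)) stop("event names must be unique")
  out
}

#' Write genomic intervals to BED
#'
#' @param events data.frame with `chrom`, `start`, `end` and optional `name`.
#' @param path output file.
#' @export
write_bed <- function(events, path) {
  cols <- events[, intersect(c("chrom", "start", "end", "name"), names(events))]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract event sequences from a reference genome
#'
#' Looks up each 0-based half-open interval in a FASTA genome and returns
#' uppercase plus-strand sequences of length `end - start`. Sequence names in
#' the FASTA are truncated at the first whitespace.
#'
#' @param events data.frame with `chrom`, `start`, `end`, `name` (as from
#'   [read_bed()]).
#' @param genome path to a FASTA file, or a named character vector of
#'   chromosome sequences.
#' @return named character vector of uppercase sequences.
#' @export
extract_event_sequences <- function(events, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    gset <- Biostrings::readDNAStringSet(genome)
    names(gset) <- sub("\\s.*$", "", names(gset))
    chrom_seqs <- stats::setNames(as.character(gset), names(gset))
  } else {
    chrom_seqs <- genome
  }
  missing <- setdiff(unique(events$chrom), names(chrom_seqs))
  if (length(missing))
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  lens <- nchar(chrom_seqs)[events$chrom]
  bad <- which(events$end > lens | events$start < 0)
  if (length(bad))
    stop("interval beyond chromosome end: ", events$name[bad[1L]])
  out <- toupper(substr(chrom_seqs[events$chrom], events$start + 1L, events$end))
  stats::setNames(unname(out), events$name)
}

#' Read TF motifs (JASPAR pfm or MEME minimal)
#'
#' Counts or probabilities are normalized to column-stochastic position
#' weight matrices (rows A, C, G, T). Normalization only: no pseudocount is
#' added.
#'
#' @param path motif file.
#' @param format `"jaspar"` or `"meme"`; default guesses from content.
#' @return a list of `motif_model` objects (fields `name`, `pwm`, `source`).
#' @export
read_motifs <- function(path, format = c("auto", "jaspar", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version|^letter-probability matrix|^MOTIF ", lines)))
      "meme" else "jaspar"
  }
  if (format == "jaspar") parse_jaspar(lines, path) else parse_meme(lines, path)
}

normalize_pwm <- function(counts, name) {
  if (nrow(counts) != 4L) stop("motif '", name, "': PWM must have 4 rows (A,C,G,T)")
  cs <- colSums(counts)
  if (any(cs <= 0)) stop("motif '", name, "': column sums to 0")
  pwm <- sweep(counts, 2L, cs, "/")
  rownames(pwm) <- DNA_BASES
  pwm
}

parse_jaspar <- function(lines, source) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR motif headers ('>') found in ", source)
  motifs <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    if (length(body) != 4L)
      stop("motif '", name, "': expected 4 base rows, got ", length(body))
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.eE+-]+", l))[[1L]]
      as.numeric(nums)
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("motif '", name, "': ragged count rows")
    counts <- do.call(rbind, rows)
    # respect explicit base labels when present (A/C/G/T row prefixes)
    labels <- toupper(substr(trimws(body), 1L, 1L))
    if (all(labels %in% DNA_BASES) && !anyDuplicated(labels))
      counts <- counts[match(DNA_BASES, labels), , drop = FALSE]
    motifs[[i]] <- structure(
      list(name = name, pwm = normalize_pwm(counts, name), source = source),
      class = "motif_model"
    )
  }
  motifs
}

parse_meme <- function(lines, source) {
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks found in ", source)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    li <- s + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix", lines[li])) li <- li + 1L
    if (li > length(lines)) stop("motif '", name, "': no letter-probability matrix")
    wm <- regmatches(lines[li], regexpr("w=\\s*[0-9]+", lines[li]))
    w <- if (length(wm)) as.integer(sub("w=\\s*", "", wm)) else NA_integer_
    rows <- list()
    li <- li + 1L
    while (li <= length(lines)) {
      nums <- suppressWarnings(as.numeric(strsplit(trimws(lines[li]), "\\s+")[[1L]]))
      if (length(nums) != 4L || anyNA(nums)) break
      rows[[length(rows) + 1L]] <- nums
      li <- li + 1L
    }
    if (!is.na(w) && length(rows) != w)
      stop("motif '", name, "': expected ", w, " rows, found ", length(rows))
    counts <- t(do.call(rbind, rows))  # MEME rows are positions
    motifs[[length(motifs) + 1L]] <- structure(
      list(name = name, pwm = normalize_pwm(counts, name), source = source),
      class = "motif_model"
    )
  }
  motifs
}

#' Construct a motif model
#'
#' @param name motif name.
#' @param pwm 4 x width matrix (rows A, C, G, T); columns are normalized to
#'   sum to 1.
#' @param source free-text provenance.
#' @return a `motif_model`.
#' @export
motif_model <- function(name, pwm, source = "user") {
  structure(list(name = name, pwm = normalize_pwm(pwm, name), source = source),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s' (width %d): %s\n", x$name, ncol(x$pwm),
              motif_consensus(x)))
  invisible(x)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs a list of `motif_model` objects.
#' @param path output file.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(m$pwm)), con)
    for (j in seq_len(ncol(m$pwm)))
      writeLines(paste(sprintf("%.6f", m$pwm[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Save a trained model
#'
#' Writes a TSV of embedding rows with typed labels (`cell:<id>`,
#' `kmer:<canonical sequence>`, `bucket:<hash row>`) at full double precision
#' plus a JSON sidecar with the feature spec, training configuration and row
#' counts. Hash-bucket rows that are exactly zero (never touched during
#' training) are omitted and restored as zeros on load, so
#' `load_model(save_model(m))` reproduces the model bit-exactly.
#'
#' @param model a `seqspace_model`.
#' @param path output TSV path; the JSON sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seqspace_model"))
  if (nrow(model$cell_embeddings) == 0L) stop("model has 0 cells")
  spec <- model$spec
  kr <- spec$kmer_rows
  bucket_rows <- which(rowSums(model$feature_embeddings[-seq_len(kr), , drop = FALSE] != 0) > 0)
  labels <- c(paste0("cell:", model$cell_ids),
              paste0("kmer:", decode_kmer_index(seq_len(kr) - 1L, spec$k)),
              paste0("bucket:", bucket_rows - 1L))
  emb <- rbind(model$cell_embeddings,
               model$feature_embeddings[seq_len(kr), , drop = FALSE],
               model$feature_embeddings[kr + bucket_rows, , drop = FALSE])
  num <- apply(emb, 2L, function(col) sprintf("%.17g", col))
  dt <- data.table::data.table(label = labels)
  for (j in seq_len(ncol(emb))) data.table::set(dt, j = paste0("d", j), value = num[, j])
  data.table::fwrite(dt, path, sep = "\t")
  cfg <- model$config
  meta <- list(
    format = "seqspace_model",
    spec = list(k = spec$k, N = spec$N, bucket = spec$bucket, P = spec$P,
                kmer_rows = kr),
    d = ncol(model$cell_embeddings),
    n_cells = nrow(model$cell_embeddings),
    n_bucket_rows_stored = length(bucket_rows),
    n_rows_total = length(labels),
    dataset = model$dataset, batch = model$batch,
    loss_trace = model$loss_trace,
    config = list(d = cfg$d, L = cfg$L, epochs = cfg$epochs,
                  examples_per_event = cfg$examples_per_event,
                  K_neg = cfg$K_neg, margin = cfg$margin, lr0 = cfg$lr0,
                  batch_aware = cfg$batch_aware, seed = cfg$seed,
                  optimizer = cfg$optimizer)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path TSV path given to [save_model()].
#' @return a `seqspace_model`.
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "seqspace_model"))
    stop("not a seqspace model sidecar: ", path, ".json")
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (nrow(dt) != meta$n_rows_total)
    stop("row count mismatch: TSV has ", nrow(dt), ", sidecar declares ",
         meta$n_rows_total, " (truncated file?)")
  d <- meta$d
  if (ncol(dt) != d + 1L) stop("embedding dimension mismatch with sidecar")
  spec <- feature_spec(k = meta$spec$k, N = meta$spec$N,
                       bucket = meta$spec$bucket, P = meta$spec$P)
  if (spec$kmer_rows != meta$spec$kmer_rows)
    stop("k in sidecar inconsistent with stored k-mer row count")
  labels <- dt$label
  emb <- as.matrix(dt[, -1L])
  type <- sub(":.*$", "", labels)
  id <- sub("^[a-z]+:", "", labels)
  is_cell <- type == "cell"; is_kmer <- type == "kmer"; is_bucket <- type == "bucket"
  if (sum(is_cell) != meta$n_cells) stop("cell row count mismatch with sidecar")
  if (sum(is_kmer) != spec$kmer_rows)
    stop("k-mer row count ", sum(is_kmer), " does not match k = ", spec$k)
  kmer_len <- unique(nchar(id[is_kmer]))
  if (!identical(kmer_len, as.integer(spec$k)) && !identical(as.numeric(kmer_len), as.numeric(spec$k)))
    stop("stored k-mer labels have length ", paste(kmer_len, collapse = ","),
         " but sidecar declares k = ", spec$k)
  kmer_idx <- canonical_kmer_index(id[is_kmer], spec$k)
  feature <- matrix(0, spec$kmer_rows + spec$bucket, d)
  feature[kmer_idx + 1L, ] <- emb[is_kmer, , drop = FALSE]
  if (any(is_bucket)) {
    bi <- as.integer(id[is_bucket])
    if (any(bi < 0 | bi >= spec$bucket)) stop("bucket row index out of range")
    feature[spec$kmer_rows + bi + 1L, ] <- emb[is_bucket, , drop = FALSE]
  }
  cells <- emb[is_cell, , drop = FALSE]
  rownames(cells) <- id[is_cell]
  cfg <- training_config(
    d = d, L = meta$config$L, epochs = meta$config$epochs,
    examples_per_event = meta$config$examples_per_event,
    K_neg = meta$config$K_neg, margin = meta$config$margin,
    lr0 = meta$config$lr0, batch_aware = meta$config$batch_aware,
    seed = meta$config$seed,
    optimizer = if (is.null(meta$config$optimizer)) "sgd" else meta$config$optimizer,
    spec = spec
  )
  structure(
    list(cell_embeddings = cells, feature_embeddings = feature, spec = spec,
         config = cfg, cell_ids = id[is_cell],
         dataset = meta$dataset, batch = meta$batch,
         loss_trace = meta$loss_trace,
         examples_skipped = NA_real_, zero_norm_pairs = NA_real_,
         n_usable_events = NA_integer_),
    class = "seqspace_model"
  )
}
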