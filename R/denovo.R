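## denovo_motifs: discover motifs from the trained embedding via 10-mers
## associated with groups of cells.

#' Embed all canonical 10-mers
#'
#' Computes the embedding of every canonical (k+2)-mer as the plain average
#' of its three constituent canonical k-mer embedding rows (no `M^P`
#' scaling). A (k+2)-mer and its reverse complement share one row. With the
#' default `k = 8` this is the table of all canonical DNA 10-mers.
#'
#' @param model a trained `seqspace_model`.
#' @param strict error when the model was not trained with `k = 8`
#'   (default `FALSE`: generalizes to (k+2)-mers with a warning).
#' @return list of class `tenmer_table`: `tenmers` (canonical strings),
#'   `embeddings` (10-mers x d), `m` (the 10-mer length used).
#' @export
embed_all_10mers <- function(model, strict = FALSE) {
  stopifnot(inherits(model, "seqspace_model"))
  k <- model$spec$k
  if (k != 8L) {
    if (strict) stop("model was trained with k = ", k, ", not 8")
    warning("model trained with k = ", k, "; using canonical ", k + 2, "-mers")
  }
  m <- k + 2L
  tab10 <- kmer_index_table(m)
  tabk <- kmer_index_table(k)
  codes <- tab10$canon_codes
  c1 <- (codes - codes %% 16) / 16
  c2 <- ((codes - codes %% 4) / 4) %% 4^k
  c3 <- codes %% 4^k
  i1 <- tabk$lut[c1 + 1] + 1L
  i2 <- tabk$lut[c2 + 1] + 1L
  i3 <- tabk$lut[c3 + 1] + 1L
  fe <- model$feature_embeddings
  emb <- (fe[i1, , drop = FALSE] + fe[i2, , drop = FALSE] +
            fe[i3, , drop = FALSE]) / 3
  tenmers <- code_to_kmer(codes, m)
  rownames(emb) <- tenmers
  structure(list(tenmers = tenmers, embeddings = emb, m = m),
            class = "tenmer_table")
}

#' Group-associated 10-mers from the bipartite cell/10-mer NN graph
#'
#' For each cell, its `K` nearest 10-mers by cosine distance; a 10-mer joins
#' a group's set when it is a neighbor of at least `ceil(freq * group size)`
#' of the group's cells.
#'
#' @param table a `tenmer_table` from [embed_all_10mers()].
#' @param cell_embeddings cells x d matrix (e.g. `model$cell_embeddings`).
#' @param groups per-cell group labels (e.g. cluster assignments).
#' @param K nearest 10-mers per cell (default 50).
#' @param freq minimum fraction of a group's cells (default 0.20).
#' @param chunk_size 10-mers scored per block (memory knob).
#' @return named list: per group, the character vector of associated 10-mers.
#' @export
group_associated_10mers <- function(table, cell_embeddings, groups, K = 50L,
                                    freq = 0.20, chunk_size = 100000L) {
  stopifnot(inherits(table, "tenmer_table"))
  n <- nrow(cell_embeddings)
  if (length(groups) != n) stop("groups must cover all cells")
  cn <- l2_normalize_rows(cell_embeddings)
  tn <- l2_normalize_rows(table$embeddings)
  nt <- nrow(tn)
  top_val <- matrix(-Inf, n, K)
  top_idx <- matrix(0L, n, K)
  start <- 1L
  while (start <= nt) {
    end <- min(start + chunk_size - 1L, nt)
    sims <- tcrossprod(cn, tn[start:end, , drop = FALSE])
    for (i in seq_len(n)) {
      v <- c(top_val[i, ], sims[i, ])
      ids <- c(top_idx[i, ], start:end)
      o <- order(v, decreasing = TRUE)[seq_len(K)]
      top_val[i, ] <- v[o]
      top_idx[i, ] <- ids[o]
    }
    start <- end + 1L
  }
  out <- list()
  group_levels <- if (is.factor(groups)) levels(groups) else unique(groups)
  for (g in group_levels) {
    cells <- which(groups == g)
    if (!length(cells)) {
      warning("group '", g, "' has no cells; skipped")
      next
    }
    thr <- ceiling(freq * length(cells))
    counts <- tabulate(top_idx[cells, , drop = FALSE], nbins = nt)
    out[[as.character(g)]] <- table$tenmers[counts >= thr]
  }
  out
}

#' Cluster 10-mers by sequence dissimilarity
#'
#' Pairwise dissimilarity `1 - best_matches/10`, where `best_matches` is the
#' maximum number of aligned identical bases over all ungapped offsets and
#' both strands; average-linkage hierarchical clustering cut at `cut`.
#' A 10-mer and its reverse complement have dissimilarity 0.
#'
#' @param tenmers character vector of (equal-length) 10-mers.
#' @param cut tree cut height on the normalized 0..1 scale (default 0.5).
#' @return integer cluster labels aligned with `tenmers`.
#' @export
cluster_10mers <- function(tenmers, cut = 0.5) {
  if (!length(tenmers)) stop("empty 10-mer set")
  if (length(tenmers) == 1L) return(1L)
  D <- cpp_kmer_dissim(tenmers)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  unname(stats::cutree(hc, h = cut))
}

## Best ungapped alignment of b against a: offset (position of b's first base
## in a's coordinates, may be negative) and strand maximizing matches.
## Ties: more matches, then smaller |offset|, then plus strand, then smaller
## offset.
best_offset <- function(a, b) {
  m <- nchar(a)
  av <- strsplit(a, "")[[1L]]
  cand <- expand.grid(offset = -(m - 1L):(m - 1L), strand = c("+", "-"),
                      stringsAsFactors = FALSE)
  cand$matches <- 0L
  for (i in seq_len(nrow(cand))) {
    bs <- if (cand$strand[i] == "+") b else revcomp(b)
    bv <- strsplit(bs, "")[[1L]]
    off <- cand$offset[i]
    lo <- max(0L, off); hi <- min(m, m + off)
    if (hi > lo) {
      ia <- (lo + 1L):hi
      cand$matches[i] <- sum(av[ia] == bv[ia - off])
    }
  }
  o <- order(-cand$matches, abs(cand$offset), cand$strand, cand$offset)
  cand[o[1L], c("offset", "strand", "matches")]
}

#' Align a 10-mer cluster and build its PWM
#'
#' Star alignment: the anchor is the member with the smallest total
#' dissimilarity to the others; every other member is placed at its best
#' ungapped offset and strand against the anchor. The PWM covers alignment
#' columns supported by at least half the members, with base frequencies plus
#' a pseudocount of 0.01. Clusters of size three or fewer yield no motif
#' (`NULL`).
#'
#' @param members character vector of 10-mers in one cluster.
#' @param name motif name.
#' @param embeddings optional 10-mers x d matrix (rownames = canonical
#'   10-mers) used to attach the motif embedding (mean of member rows).
#' @param pseudocount per-base pseudocount (default 0.01).
#' @return a `denovo_motif` (also a `motif_model`): `name`, `pwm`,
#'   `member_10mers`, `embedding`; or `NULL` for clusters of size <= 3.
#' @export
align_and_build_pwm <- function(members, name = "denovo", embeddings = NULL,
                                pseudocount = 0.01) {
  if (length(members) <= 3L) {
    message("cluster of size ", length(members), " discarded (need > 3)")
    return(NULL)
  }
  m <- nchar(members[1L])
  D <- cpp_kmer_dissim(members)
  anchor <- which.min(rowSums(D))
  placements <- data.frame(seq = members, offset = 0L, strand = "+",
                           stringsAsFactors = FALSE)
  for (i in seq_along(members)) {
    if (i == anchor) next
    bo <- best_offset(members[anchor], members[i])
    placements$offset[i] <- bo$offset
    placements$strand[i] <- bo$strand
  }
  lo <- min(placements$offset)
  width <- max(placements$offset) + m - lo
  counts <- matrix(0, 4L, width, dimnames = list(DNA_BASES, NULL))
  coverage <- integer(width)
  for (i in seq_along(members)) {
    s <- if (placements$strand[i] == "+") members[i] else revcomp(members[i])
    cols <- placements$offset[i] - lo + seq_len(m)
    bases <- strsplit(s, "")[[1L]]
    for (j in seq_len(m)) {
      counts[bases[j], cols[j]] <- counts[bases[j], cols[j]] + 1
      coverage[cols[j]] <- coverage[cols[j]] + 1L
    }
  }
  keep <- coverage >= length(members) / 2
  counts <- counts[, keep, drop = FALSE] + pseudocount
  pwm <- sweep(counts, 2L, colSums(counts), "/")
  emb <- NULL
  if (!is.null(embeddings)) {
    canon <- canonical_orientation(members)
    emb <- colMeans(embeddings[canon, , drop = FALSE])
  }
  structure(list(name = name, pwm = pwm, source = "denovo",
                 member_10mers = members, embedding = emb),
            class = c("denovo_motif", "motif_model"))
}

#' Best-offset correlation between two PWMs
#'
#' Pearson correlation of the stacked base probabilities over the overlapping
#' columns, maximized over ungapped offsets and both strands. Used to compare
#' discovered motifs with reference PWMs.
#'
#' @param a,b `motif_model`s or 4 x width PWM matrices.
#' @param min_overlap smallest column overlap considered (default 4).
#' @return list with `correlation`, `offset`, `strand`.
#' @export
pwm_correlation <- function(a, b, min_overlap = 4L) {
  pa <- if (inherits(a, "motif_model")) a$pwm else a
  pb <- if (inherits(b, "motif_model")) b$pwm else b
  rc_pwm <- function(p) p[4:1, rev(seq_len(ncol(p))), drop = FALSE]
  best <- list(correlation = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    pbs <- if (strand == "+") pb else rc_pwm(pb)
    for (off in -(ncol(pbs) - min_overlap):(ncol(pa) - min_overlap)) {
      ia <- intersect(seq_len(ncol(pa)), off + seq_len(ncol(pbs)))
      if (length(ia) < min_overlap) next
      ib <- ia - off
      r <- suppressWarnings(stats::cor(as.numeric(pa[, ia]),
                                       as.numeric(pbs[, ib])))
      if (!is.na(r) && r > best$correlation)
        best <- list(correlation = r, offset = off, strand = strand)
    }
  }
  best
}

#' De novo motif discovery from a trained model
#'
#' End-to-end pipeline: embed all canonical 10-mers, find the 10-mers
#' associated with each cell group via the bipartite K-NN graph, cluster them
#' by sequence dissimilarity, and build one PWM per cluster of size greater
#' than three. Deterministic for a fixed model input.
#'
#' @param model a trained `seqspace_model`.
#' @param groups per-cell group labels (e.g. cluster assignments).
#' @param K nearest 10-mers per cell (default 50).
#' @param freq group-frequency threshold (default 0.20).
#' @param cut tree cut height (default 0.5).
#' @param table optional precomputed [embed_all_10mers()] result.
#' @return list of `denovo_motif` objects; each carries its
#'   `source_cell_group` field.
#' @export
discover_motifs <- function(model, groups, K = 50L, freq = 0.20, cut = 0.5,
                            table = NULL) {
  if (is.null(table)) table <- embed_all_10mers(model)
  sets <- group_associated_10mers(table, model$cell_embeddings, groups,
                                  K = K, freq = freq)
  motifs <- list()
  for (g in names(sets)) {
    tm <- sets[[g]]
    if (length(tm) < 2L) next
    cl <- cluster_10mers(tm, cut = cut)
    for (ci in sort(unique(cl))) {
      members <- tm[cl == ci]
      if (length(members) <= 3L) next
      mot <- align_and_build_pwm(
        members, name = sprintf("denovo_%s_%d", g, ci),
        embeddings = table$embeddings
      )
      if (is.null(mot)) next
      mot$source_cell_group <- g
      motifs[[mot$name]] <- mot
    }
  }
  motifs
}
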