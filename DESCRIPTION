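Package: seqspace
Title: Sequence-Informed Co-Embedding of Cells and DNA k-mers for Single-Cell ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a joint latent space for cells and DNA k-mers from
    single-cell ATAC-seq data. Training examples are short sequences sampled
    from accessible events, represented as bags of canonical (reverse-complement
    collapsed) k-mers plus hashed k-mer-pair context features, and optimized
    against positive and negative cells with a cosine margin ranking loss and
    K-negative sampling. The trained space supports transcription-factor motif
    activity scoring, de novo motif discovery from cell-associated 10-mers,
    shared-nearest-neighbor clustering, and a benchmarking suite with
    biological-conservation and batch-correction scores, bootstrap confidence
    intervals and confidence-interval-inversion tests. A self-contained
    synthetic scATAC-seq generator with planted motifs and batch effects
    supports testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    data.table,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
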