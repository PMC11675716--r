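Package: seq2expr
Title: Gene Expression Prediction from DNA Language-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts per-gene expression levels from long genomic windows
    around transcription start sites. Windows are fragmented by overlapping
    k-mer tokenization with token-level chunking, or by base-pair sliding
    windows; each fragment is embedded with a pluggable DNA language-model
    backend, mean-pooled, and stacked into a fixed-shape matrix per gene.
    A multi-branch one-dimensional convolutional network with batch
    normalization, GELU activations and dropout regresses expression from
    these matrices, optionally fused with mRNA half-life and transcription
    factor target features. Includes strand-aware window extraction from
    FASTA genomes, a deterministic hash-keyed mock embedding backend so the
    whole pipeline is testable without pre-trained weights, an on-disk
    embedding cache, a training harness with early stopping and R-squared
    evaluation over repeated runs and feature ablations, and a planted-signal
    synthetic dataset generator with a closed-form R-squared ceiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
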