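#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GenomicWindow: a strand-oriented sequence window around one gene's anchor
#'
#' Holds the extracted window for a single gene, always reported in gene
#' orientation (reverse-complemented for minus-strand genes), so that
#' `upstreamBp` bases precede the anchor in the 5' direction of the gene.
#'
#' @slot geneId single gene identifier.
#' @slot sequence uppercase character string over the alphabet A, C, G, T, N.
#' @slot upstreamBp number of bases 5' of the anchor.
#' @slot downstreamBp number of bases from the anchor onwards (the anchor base
#'   itself is the first downstream base).
#' @export
setClass("GenomicWindow",
  representation(
    geneId       = "character",
    sequence     = "character",
    upstreamBp   = "integer",
    downstreamBp = "integer"
  )
)

setValidity("GenomicWindow", function(object) {
  msg <- character(0)
  if (length(object@sequence) != 1L) {
    msg <- c(msg, "sequence must be a single string")
  } else {
    if (nchar(object@sequence) != object@upstreamBp + object@downstreamBp) {
      msg <- c(msg, sprintf(
        "sequence length (%d) != upstreamBp + downstreamBp (%d)",
        nchar(object@sequence), object@upstreamBp + object@downstreamBp))
    }
    if (grepl("[^ACGTN]", object@sequence)) {
      msg <- c(msg, "sequence contains characters outside {A,C,G,T,N}")
    }
  }
  if (object@upstreamBp < 0L || object@downstreamBp < 0L) {
    msg <- c(msg, "upstreamBp and downstreamBp must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' GeneTable: joined per-gene windows, auxiliary features and labels
#'
#' Row i of every slot refers to the same gene. `windows` is a named list of
#' window sets (one element per window specification, e.g. a 10.5-kb and a
#' 50-kb window), each a character vector parallel to `geneId`. Auxiliary
#' features are optional but uniform across genes: either every gene has a
#' half-life vector or none does.
#'
#' @slot geneId character vector of unique gene identifiers, in label-file
#'   order.
#' @slot windows named list of character vectors of window sequences.
#' @slot windowSpecs named list of `c(up, down)` integer pairs describing each
#'   window set.
#' @slot halflife numeric matrix with 8 columns of mRNA half-life features, or
#'   NULL.
#' @slot tf numeric matrix with 181 binary transcription-factor-target
#'   columns, or NULL.
#' @slot labels numeric matrix of expression labels (1 column for median
#'   expression, or one column per tissue).
#' @export
setClass("GeneTable",
  representation(
    geneId      = "character",
    windows     = "list",
    windowSpecs = "list",
    halflife    = "matrixOrNULL",
    tf          = "matrixOrNULL",
    labels      = "matrix"
  )
)

setValidity("GeneTable", function(object) {
  n <- length(object@geneId)
  msg <- character(0)
  if (anyDuplicated(object@geneId)) msg <- c(msg, "duplicate gene ids")
  for (nm in names(object@windows)) {
    if (length(object@windows[[nm]]) != n) {
      msg <- c(msg, sprintf("window set '%s' has wrong length", nm))
    }
  }
  if (!identical(sort(names(object@windows)), sort(names(object@windowSpecs)))) {
    msg <- c(msg, "windows and windowSpecs must share names")
  }
  if (!is.null(object@halflife)) {
    if (nrow(object@halflife) != n) msg <- c(msg, "halflife row count mismatch")
    if (ncol(object@halflife) != 8L) {
      msg <- c(msg, sprintf("halflife must have 8 columns, got %d",
                            ncol(object@halflife)))
    }
  }
  if (!is.null(object@tf)) {
    if (nrow(object@tf) != n) msg <- c(msg, "tf row count mismatch")
    if (ncol(object@tf) != 181L) {
      msg <- c(msg, sprintf("tf must have 181 columns, got %d", ncol(object@tf)))
    }
  }
  if (nrow(object@labels) != n) msg <- c(msg, "labels row count mismatch")
  if (length(msg)) msg else TRUE
})

#' EmbedderBackend: contract for fragment embedding backends
#'
#' A backend turns one fragment into an `[n_tokens x dim]` real matrix,
#' deterministically. `mode` selects the fragmentation scheme the backend
#' expects: `"token_chunk"` for overlapping-k-mer token chunks (the
#' DNABERT-style route) or `"bp_window"` for base-pair sliding windows (the
#' DNABERT-2-style route, where the backend applies its own tokenizer).
#'
#' @slot name backend identifier used in caches and embedding matrices.
#' @slot mode `"token_chunk"` or `"bp_window"`.
#' @slot dim embedding width D.
#' @slot maxTokens capacity per embedding call.
#' @export
setClass("EmbedderBackend",
  representation(
    name      = "character",
    mode      = "character",
    dim       = "integer",
    maxTokens = "integer",
    "VIRTUAL"
  )
)

setValidity("EmbedderBackend", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("token_chunk", "bp_window")) {
    msg <- c(msg, "mode must be 'token_chunk' or 'bp_window'")
  }
  if (object@dim <= 0L) msg <- c(msg, "dim must be positive")
  if (object@maxTokens <= 0L) msg <- c(msg, "maxTokens must be positive")
  if (length(msg)) msg else TRUE
})

#' MockEmbedder: deterministic hash-keyed embedding backend
#'
#' Embeds each token as a pseudo-random vector drawn from a generator keyed by
#' a hash of the token string and the backend seed. The same token always maps
#' to the same vector, across calls and across processes, so the full pipeline
#' is reproducible without pre-trained weights. Token vectors are memoised in
#' an environment for speed.
#'
#' @slot seed integer mixed into every token's generator key.
#' @slot k k-mer size of the backend's own tokenizer (used directly in
#'   `token_chunk` mode; applied to each base-pair window in `bp_window` mode).
#' @slot tokenCache environment memoising token vectors.
#' @export
setClass("MockEmbedder",
  contains = "EmbedderBackend",
  representation(
    seed       = "integer",
    k          = "integer",
    tokenCache = "environment"
  )
)

#' EmbeddingMatrix: pooled fragment embeddings for one gene window
#'
#' One row per fragment: the mean-pooled embedding of that fragment under one
#' backend. Row order follows fragment order along the window.
#'
#' @slot geneId gene identifier.
#' @slot backend backend name the matrix was computed with.
#' @slot matrix `[n_fragments x dim]` numeric matrix, all values finite.
#' @slot spans two-column integer matrix of 0-based half-open bp spans, one
#'   row per fragment.
#' @export
setClass("EmbeddingMatrix",
  representation(
    geneId  = "character",
    backend = "character",
    matrix  = "matrix",
    spans   = "matrix"
  )
)

setValidity("EmbeddingMatrix", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@matrix))) msg <- c(msg, "non-finite embedding values")
  if (nrow(object@spans) != nrow(object@matrix)) {
    msg <- c(msg, "one span per fragment required")
  }
  if (ncol(object@spans) != 2L) msg <- c(msg, "spans must have two columns")
  if (length(msg)) msg else TRUE
})

#' ExpressionCNN: multi-branch convolutional expression regressor
#'
#' Opaque trainable model. `config` describes the architecture (branches,
#' kernel sizes, dropout rates, auxiliary dims, output width), `params` holds
#' the trainable arrays, and `state` the batch-normalization running moments.
#' Eval-mode forward passes are deterministic for fixed weights and inputs.
#'
#' @slot config list describing the architecture.
#' @slot params list of trainable parameter arrays.
#' @slot state list of batch-norm running statistics.
#' @export
setClass("ExpressionCNN",
  representation(
    config = "list",
    params = "list",
    state  = "list"
  )
)

#' EvalReport: per-run and aggregated R-squared results
#'
#' @slot runs data.frame with one row per (condition, run): seed and test
#'   R-squared.
#' @slot aggregate data.frame with one row per condition: min, avg, max test
#'   R-squared over runs.
#' @slot perLabel data.frame of per-label R-squared values (per-tissue mode),
#'   or an empty data.frame.
#' @slot nRuns number of runs per condition.
#' @export
setClass("EvalReport",
  representation(
    runs      = "data.frame",
    aggregate = "data.frame",
    perLabel  = "data.frame",
    nRuns     = "integer"
  )
)

setValidity("EvalReport", function(object) {
  agg <- object@aggregate
  if (nrow(agg) &&
      !all(agg$min <= agg$avg + 1e-12 & agg$avg <= agg$max + 1e-12)) {
    return("aggregate must satisfy min <= avg <= max")
  }
  TRUE
})
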