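#' Gene identifiers of a container
#' @param x a GeneTable or EmbeddingMatrix.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Expression labels of a GeneTable
#' @param x a GeneTable.
#' @return numeric matrix, one row per gene.
#' @export
setGeneric("expressionLabels", function(x) standardGeneric("expressionLabels"))

#' mRNA half-life feature matrix
#' @param x a GeneTable.
#' @return numeric matrix with 8 columns, or NULL when absent.
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))

#' Transcription-factor target matrix
#' @param x a GeneTable.
#' @return binary matrix with 181 columns, or NULL when absent.
#' @export
setGeneric("tfTargets", function(x) standardGeneric("tfTargets"))

#' Window sequences of a GeneTable
#' @param x a GeneTable.
#' @param which name of the window set (defaults to the first).
#' @return character vector of sequences parallel to `geneIds(x)`.
#' @export
setGeneric("windowSequences",
           function(x, which = NULL) standardGeneric("windowSequences"))

#' Embed one fragment with a backend
#'
#' Returns one embedding row per content token of the fragment.
#'
#' @param backend an [EmbedderBackend-class].
#' @param fragment a fragment as produced by [chunkTokens()] or
#'   [slidingFragments()].
#' @return numeric matrix of shape `[n_tokens x dim(backend)]`.
#' @export
setGeneric("embedFragment",
           function(backend, fragment) standardGeneric("embedFragment"))

#' Embed a whole window into a pooled fragment matrix
#'
#' Fragments the window according to the backend's mode, embeds each fragment,
#' mean-pools it, and stacks the pooled vectors into an [EmbeddingMatrix-class].
#'
#' @param backend an [EmbedderBackend-class].
#' @param window a [GenomicWindow-class] or a plain character sequence.
#' @param geneId gene identifier recorded in the result (taken from the window
#'   when it is a GenomicWindow).
#' @param chunkSize token budget per fragment in `token_chunk` mode.
#' @param windowBp,stepBp sliding-window geometry in `bp_window` mode.
#' @return an [EmbeddingMatrix-class].
#' @export
setGeneric("sequenceEmbedding",
  function(backend, window, geneId = NULL, chunkSize = 500L,
           windowBp = 2000L, stepBp = 500L)
    standardGeneric("sequenceEmbedding"))
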