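#' On-disk embedding cache
#'
#' Embedding matrices are computed once and stored in a directory-backed array
#' store keyed by `(gene_id, backend)`, so that training never has to call an
#' embedding backend. Each entry is one serialized array file under
#' `<path>/<backend>/<gene_id>.rds`; a `manifest.tsv` at the cache root lists
#' every entry with its shape. The round trip is lossless: shapes, spans and
#' values are preserved exactly.
#'
#' @param path cache directory (created on first store).
#' @param emb an [EmbeddingMatrix-class] to store.
#' @param geneId,backend key of the entry to load. `backend` may be an
#'   [EmbedderBackend-class] or a backend name.
#' @return `cacheStore` invisibly returns the entry file path; `cacheLoad`
#'   returns the stored [EmbeddingMatrix-class]; `cacheContains` a logical;
#'   `cacheManifest` a data.frame of all entries.
#' @name embeddingCache
NULL

backendName <- function(backend) {
  if (is(backend, "EmbedderBackend")) backend@name else as.character(backend)
}

cacheEntryPath <- function(path, geneId, backend) {
  file.path(path, backendName(backend), paste0(geneId, ".rds"))
}

#' @rdname embeddingCache
#' @export
cacheStore <- function(path, emb) {
  stopifnot(is(emb, "EmbeddingMatrix"))
  f <- cacheEntryPath(path, emb@geneId, emb@backend)
  dir.create(dirname(f), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dirname(f))) stop("cache path is not writable: ", path)
  saveRDS(emb, f)
  manifestAdd(path, emb)
  invisible(f)
}

## Append-only manifest; cacheManifest() deduplicates keeping the last entry.
manifestAdd <- function(path, emb) {
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf)) {
    cat("gene_id\tbackend\tn_fragments\tdim\n", file = mf)
  }
  cat(sprintf("%s\t%s\t%d\t%d\n", emb@geneId, emb@backend,
              nrow(emb@matrix), ncol(emb@matrix)),
      file = mf, append = TRUE)
}

#' @rdname embeddingCache
#' @export
cacheLoad <- function(path, geneId, backend) {
  if (!dir.exists(path)) {
    stop(errorCondition(paste0("embedding cache not found: ", path),
                        class = c("cacheIOError", "error", "condition")))
  }
  f <- cacheEntryPath(path, geneId, backend)
  if (!file.exists(f)) {
    stop(errorCondition(
      sprintf("no cached embedding for gene '%s' under backend '%s'",
              geneId, backendName(backend)),
      class = c("cacheMissError", "error", "condition")))
  }
  readRDS(f)
}

#' @rdname embeddingCache
#' @export
cacheContains <- function(path, geneId, backend) {
  file.exists(cacheEntryPath(path, geneId, backend))
}

#' @rdname embeddingCache
#' @export
cacheManifest <- function(path) {
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf)) {
    return(data.frame(gene_id = character(0), backend = character(0),
                      n_fragments = integer(0), dim = integer(0)))
  }
  m <- utils::read.delim(mf, stringsAsFactors = FALSE)
  key <- paste(m$gene_id, m$backend, sep = "\r")
  m[!duplicated(key, fromLast = TRUE), , drop = FALSE]
}

#' Embed a gene table into a cache
#'
#' Computes [sequenceEmbedding()] for every gene of one window set under one
#' or more backends and stores the results. Skips entries already present.
#'
#' @param geneTable a [GeneTable-class].
#' @param backends list of [EmbedderBackend-class] objects.
#' @param path cache directory.
#' @param which window set name (defaults to the first).
#' @param ... passed to [sequenceEmbedding()].
#' @return the cache path, invisibly.
#' @export
cachePopulate <- function(geneTable, backends, path, which = NULL, ...) {
  if (is(backends, "EmbedderBackend")) backends <- list(backends)
  seqs <- windowSequences(geneTable, which)
  ids <- geneIds(geneTable)
  for (be in backends) {
    for (i in seq_along(ids)) {
      if (cacheContains(path, ids[i], be)) next
      cacheStore(path, sequenceEmbedding(be, seqs[i], geneId = ids[i], ...))
    }
  }
  invisible(path)
}
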