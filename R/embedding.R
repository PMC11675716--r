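## Stable 31-base polynomial string hash modulo 2^31 - 1; pure arithmetic on
## doubles so it is identical across platforms and processes.
strHash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

withPreservedRNG <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Deterministic mock token embedding
#'
#' Draws a pseudo-random vector from a generator keyed by a hash of the token
#' string mixed with `seed`. The same (token, dim, seed) triple yields a
#' bitwise-identical vector in every call and every process; distinct tokens
#' collide only with hash probability ~2^-31. Tokens containing N are embedded
#' like any other token. The caller's RNG state is left untouched.
#'
#' @param token non-empty token string.
#' @param dim embedding width.
#' @param seed integer mixed into the key.
#' @return numeric vector of length `dim`.
#' @export
mockEmbedToken <- function(token, dim = 768L, seed = 0L) {
  stopifnot(is.character(token), length(token) == 1L, nchar(token) > 0L)
  key <- (strHash(token) + as.numeric(seed) * 1000003) %% 2147483647
  withPreservedRNG({
    set.seed(as.integer(key))
    stats::rnorm(as.integer(dim))
  })
}

#' Construct a mock embedding backend
#'
#' A [MockEmbedder-class] embeds every content token through
#' [mockEmbedToken()], memoising token vectors. In `token_chunk` mode it
#' consumes token-chunk fragments directly (DNABERT-style); in `bp_window`
#' mode it applies its own overlapping k-mer tokenizer to each base-pair
#' window before embedding (standing in for a backend with an internal
#' tokenizer, as DNABERT-2's BPE is).
#'
#' @param mode `"token_chunk"` or `"bp_window"`.
#' @param dim embedding width (768 matches the real backends; use a small
#'   value such as 16 for fast experiments).
#' @param k k-mer size of the backend tokenizer.
#' @param seed integer key component, part of the backend identity.
#' @param maxTokens capacity per fragment; defaults to 512 tokens in
#'   `token_chunk` mode and 2048 in `bp_window` mode.
#' @param name backend name used in caches; defaults to a mode/dim/seed tag.
#' @return a [MockEmbedder-class].
#' @export
mockEmbedder <- function(mode = c("token_chunk", "bp_window"), dim = 768L,
                         k = 6L, seed = 0L, maxTokens = NULL, name = NULL) {
  mode <- match.arg(mode)
  if (is.null(maxTokens)) {
    maxTokens <- if (mode == "token_chunk") 512L else 2048L
  }
  if (is.null(name)) {
    name <- sprintf("mock-%s-d%d-s%d", mode, as.integer(dim), as.integer(seed))
  }
  new("MockEmbedder",
      name = name, mode = mode, dim = as.integer(dim),
      maxTokens = as.integer(maxTokens), seed = as.integer(seed),
      k = as.integer(k), tokenCache = new.env(parent = emptyenv()))
}

## Memoised lookup: returns an [n x dim] matrix of token vectors.
mockTokenMatrix <- function(backend, tokens) {
  cache <- backend@tokenCache
  uniq <- unique(tokens)
  have <- vapply(uniq, exists, TRUE, envir = cache, inherits = FALSE)
  for (t in uniq[!have]) {
    assign(t, mockEmbedToken(t, backend@dim, backend@seed), envir = cache)
  }
  vecs <- mget(uniq, envir = cache)               # list of dim-vectors
  m <- matrix(unlist(vecs, use.names = FALSE), ncol = backend@dim, byrow = TRUE)
  m[match(tokens, uniq), , drop = FALSE]
}

fragmentTokens <- function(backend, fragment) {
  if (fragment$kind == "token_chunk") {
    fragment$tokens
  } else {
    kmerTokenize(fragment$sequence, backend@k)
  }
}

#' @describeIn MockEmbedder-class embed one fragment; one row per content
#'   token.
#' @param backend,fragment see [embedFragment()].
setMethod("embedFragment", "MockEmbedder", function(backend, fragment) {
  tokens <- fragmentTokens(backend, fragment)
  if (length(tokens) == 0L) stop("fragment has no tokens to embed")
  if (length(tokens) > backend@maxTokens) {
    stop(sprintf("fragment of %d tokens exceeds backend capacity %d; re-chunk",
                 length(tokens), backend@maxTokens))
  }
  mockTokenMatrix(backend, tokens)
})

#' Mean pooling over token embeddings
#'
#' Component-wise arithmetic mean over the rows of an `[n_tokens x dim]`
#' matrix, collapsing a fragment to one fixed-width vector.
#'
#' @param m non-empty numeric matrix.
#' @return numeric vector of length `ncol(m)`.
#' @export
meanPool <- function(m) {
  if (!is.matrix(m) || nrow(m) == 0L) stop("meanPool requires a non-empty matrix")
  colMeans(m)
}

setMethod("sequenceEmbedding", "EmbedderBackend",
  function(backend, window, geneId = NULL, chunkSize = 500L,
           windowBp = 2000L, stepBp = 500L) {
    if (is(window, "GenomicWindow")) {
      if (is.null(geneId)) geneId <- window@geneId
      seqStr <- window@sequence
    } else {
      stopifnot(is.character(window), length(window) == 1L)
      seqStr <- window
      if (is.null(geneId)) geneId <- NA_character_
    }
    frags <- if (backend@mode == "token_chunk") {
      chunkTokens(kmerTokenize(seqStr, backend@k), chunkSize, k = backend@k)
    } else {
      slidingFragments(seqStr, windowBp, stepBp)
    }
    if (length(frags) == 0L) {
      stop(sprintf("window of %d bp produced no fragments", nchar(seqStr)))
    }
    pooled <- vapply(frags, function(f) meanPool(embedFragment(backend, f)),
                     numeric(backend@dim))
    mat <- matrix(t(pooled), nrow = length(frags), ncol = backend@dim)
    spans <- cbind(start = vapply(frags, `[[`, 0L, "start"),
                   end = vapply(frags, `[[`, 0L, "end"))
    expected <- if (backend@mode == "token_chunk") {
      tokenChunkCount(nchar(seqStr), backend@k, chunkSize)
    } else {
      bpWindowCount(nchar(seqStr), windowBp, stepBp)
    }
    stopifnot(nrow(mat) == expected)
    new("EmbeddingMatrix", geneId = as.character(geneId),
        backend = backend@name, matrix = mat, spans = spans)
  })

#' @describeIn EmbeddingMatrix-class gene id accessor.
#' @param x an EmbeddingMatrix.
setMethod("geneIds", "EmbeddingMatrix", function(x) x@geneId)

#' Pooled fragment matrix of an EmbeddingMatrix
#' @param x an [EmbeddingMatrix-class].
#' @return numeric `[n_fragments x dim]` matrix.
#' @export
embeddingMatrix <- function(x) {
  stopifnot(is(x, "EmbeddingMatrix"))
  x@matrix
}

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix gene=%s backend=%s [%d x %d]\n",
              object@geneId, object@backend,
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "MockEmbedder", function(object) {
  cat(sprintf("MockEmbedder '%s' mode=%s dim=%d k=%d maxTokens=%d seed=%d\n",
              object@name, object@mode, object@dim, object@k,
              object@maxTokens, object@seed))
})
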