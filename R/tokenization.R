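#' Overlapping k-mer tokenization
#'
#' Emits one token per position: token i is `substr(sequence, i, i + k - 1)`,
#' so consecutive tokens overlap by `k - 1` bases. A sequence shorter than `k`
#' yields an empty token vector. For a source of length L >= k the token count
#' is exactly `L - k + 1`.
#'
#' @param sequence a single character string.
#' @param k k-mer size (>= 1).
#' @return character vector of k-length tokens, possibly empty.
#' @examples
#' kmerTokenize("ACGTTCGA", 6)  # "ACGTTC" "CGTTCG" "GTTCGA"
#' @export
kmerTokenize <- function(sequence, k = 6L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  L <- nchar(sequence)
  if (L < k) return(character(0))
  n <- L - k + 1L
  substring(sequence, seq_len(n), seq_len(n) + k - 1L)
}

newFragment <- function(kind, start, end, tokens = NULL, sequence = NULL) {
  structure(
    list(kind = kind, start = as.integer(start), end = as.integer(end),
         tokens = tokens, sequence = sequence),
    class = "Fragment")
}

#' @export
print.Fragment <- function(x, ...) {
  n <- if (x$kind == "token_chunk") length(x$tokens) else nchar(x$sequence)
  cat(sprintf("<Fragment %s [%d,%d) %s=%d>\n", x$kind, x$start, x$end,
              if (x$kind == "token_chunk") "tokens" else "bp", n))
  invisible(x)
}

#' Greedy token-level chunking
#'
#' Splits a token stream left to right into `floor(N / chunkSize)` full chunks
#' plus one remainder chunk when `N %% chunkSize != 0`. The concatenation of
#' all chunks reproduces the input token stream. Because tokens are
#' overlapping k-mers of the same window, the bp spans of adjacent chunks
#' overlap by `k - 1` bases: a 10,500-bp window tokenized at k = 6 gives
#' 10,495 tokens and, at `chunkSize = 500`, 20 chunks of 500 tokens (505 bp
#' each) plus one of 495 tokens (500 bp).
#'
#' @param tokens character vector of k-length tokens from [kmerTokenize()].
#' @param chunkSize maximum tokens per chunk (>= 1).
#' @param k k-mer size, inferred from the first token when omitted; used only
#'   to annotate bp spans.
#' @return list of token-chunk fragments; empty list for empty input.
#' @export
chunkTokens <- function(tokens, chunkSize = 500L, k = NULL) {
  chunkSize <- as.integer(chunkSize)
  if (chunkSize < 1L) stop("chunkSize must be >= 1")
  n <- length(tokens)
  if (n == 0L) return(list())
  if (is.null(k)) k <- nchar(tokens[[1L]])
  k <- as.integer(k)
  starts <- seq.int(1L, n, by = chunkSize)
  lapply(starts, function(s) {
    e <- min(s + chunkSize - 1L, n)
    # bp span in 0-based half-open window coordinates
    newFragment("token_chunk",
                start = s - 1L, end = (e - 1L) + k,
                tokens = tokens[s:e])
  })
}

#' Base-pair sliding-window fragmentation
#'
#' Windows of `windowBp` bases starting at 0, `stepBp`, `2 * stepBp`, ...;
#' when `(L - windowBp) %% stepBp != 0` a final window anchored at
#' `L - windowBp` is appended so coverage reaches the sequence end. A sequence
#' shorter than `windowBp` degrades to a single window holding the whole
#' sequence. A 10,500-bp sequence at window 2,000 and step 500 yields 18
#' fragments.
#'
#' @param sequence single character string.
#' @param windowBp window length in bp (>= 1).
#' @param stepBp step between window starts in bp (>= 1).
#' @return list of bp-window fragments with 0-based half-open spans.
#' @export
slidingFragments <- function(sequence, windowBp = 2000L, stepBp = 500L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  windowBp <- as.integer(windowBp)
  stepBp <- as.integer(stepBp)
  if (windowBp < 1L || stepBp < 1L) stop("windowBp and stepBp must be >= 1")
  L <- nchar(sequence)
  if (L <= windowBp) {
    return(list(newFragment("bp_window", 0L, L, sequence = sequence)))
  }
  starts <- seq.int(0L, L - windowBp, by = stepBp)
  if ((L - windowBp) %% stepBp != 0L) starts <- c(starts, L - windowBp)
  lapply(starts, function(s) {
    newFragment("bp_window", s, s + windowBp,
                sequence = substr(sequence, s + 1L, s + windowBp))
  })
}

#' Predicted fragment counts
#'
#' Closed-form fragment counts for each fragmentation scheme, used for shape
#' checks without materializing fragments.
#'
#' @param L window length in bp.
#' @param k k-mer size (`token_chunk` scheme).
#' @param chunkSize tokens per chunk (`token_chunk` scheme).
#' @param windowBp,stepBp geometry (`bp_window` scheme).
#' @return integer fragment count.
#' @export
tokenChunkCount <- function(L, k = 6L, chunkSize = 500L) {
  nTok <- max(0L, as.integer(L) - as.integer(k) + 1L)
  as.integer(ceiling(nTok / as.integer(chunkSize)))
}

#' @rdname tokenChunkCount
#' @export
bpWindowCount <- function(L, windowBp = 2000L, stepBp = 500L) {
  L <- as.integer(L); windowBp <- as.integer(windowBp); stepBp <- as.integer(stepBp)
  if (L <= windowBp) return(1L)
  n <- (L - windowBp) %/% stepBp + 1L
  if ((L - windowBp) %% stepBp != 0L) n <- n + 1L
  n
}

#' Fragment manifest
#'
#' Tabulates a fragment list for audit: index, kind, bp span and token count.
#'
#' @param fragments list of fragments.
#' @param geneId optional id column value.
#' @return data.frame with one row per fragment.
#' @export
fragmentManifest <- function(fragments, geneId = NA_character_) {
  data.frame(
    gene_id = geneId,
    fragment_index = seq_along(fragments),
    kind = vapply(fragments, `[[`, "", "kind"),
    start = vapply(fragments, `[[`, 0L, "start"),
    end = vapply(fragments, `[[`, 0L, "end"),
    n_tokens = vapply(fragments, function(f) {
      if (f$kind == "token_chunk") length(f$tokens) else NA_integer_
    }, 0L),
    stringsAsFactors = FALSE)
}
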