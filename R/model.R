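branchConfig <- function(shape, channels, kernel, dropout) {
  nFragments <- as.integer(shape[[1L]])
  kernel <- as.integer(kernel)
  if (kernel > nFragments) {
    stop(sprintf("kernel size %d exceeds fragment count %d", kernel, nFragments))
  }
  list(nFragments = nFragments, dim = as.integer(shape[[2L]]),
       channels = as.integer(channels), kernel = kernel,
       dropout = as.numeric(dropout))
}

newExpressionCNN <- function(config, seed = NULL) {
  for (br in config$branches) {
    if (br$dropout < 0 || br$dropout >= 1) stop("dropout rates must be in [0,1)")
  }
  if (config$headDropout < 0 || config$headDropout >= 1) {
    stop("dropout rates must be in [0,1)")
  }
  if (config$nOutputs < 1L) stop("nOutputs must be >= 1")
  new("ExpressionCNN",
      config = config,
      params = initParams(config, seed),
      state = list(bn = initBnState(config)))
}

#' Build the dual/single-branch model for 10.5-kb-class inputs
#'
#' One branch per enabled embedding backend. Each branch applies a 1-D
#' convolution (64 channels, kernel 3) over the fragment axis of its pooled
#' embedding matrix, then batch normalization, GELU, dropout and a global max
#' over fragment positions, producing a 64-vector. Branch vectors and any
#' auxiliary features (half-life, TF targets) are concatenated and passed
#' through a 64-unit fully connected layer with batch normalization, GELU and
#' dropout, then a linear output layer.
#'
#' With both backends enabled the three dropout rates (0.6, 0.4, 0.2) go to
#' branch 1, branch 2 and the head; with a single backend the rates are
#' (0.6, 0.2) for the branch and the head.
#'
#' @param useDnabert,useDnabert2 enable the overlapping-k-mer chunk branch and
#'   the bp-sliding-window branch; at least one must be TRUE.
#' @param auxDims integer vector of auxiliary feature widths fused before the
#'   fully connected layer, e.g. `c(8, 181)`.
#' @param nOutputs number of regression outputs (1 for median expression, 57
#'   for per-tissue labels with a multi-output head).
#' @param dnabertShape,dnabert2Shape `(n_fragments, dim)` of each branch
#'   input; defaults are the canonical 10,500-bp shapes `[21, 768]` and
#'   `[18, 768]`.
#' @param channels convolution channels per branch.
#' @param fcUnits width of the fully connected layer.
#' @param reduce reduction over fragment positions before concatenation,
#'   `"max"` (default) or `"mean"`.
#' @param seed optional integer seed for weight initialization.
#' @return an [ExpressionCNN-class].
#' @export
buildModel10500 <- function(useDnabert = TRUE, useDnabert2 = TRUE,
                            auxDims = integer(0), nOutputs = 1L,
                            dnabertShape = c(21L, 768L),
                            dnabert2Shape = c(18L, 768L),
                            channels = 64L, fcUnits = 64L,
                            reduce = c("max", "mean"), seed = NULL) {
  reduce <- match.arg(reduce)
  if (!useDnabert && !useDnabert2) {
    stop("at least one embedding branch must be enabled")
  }
  dual <- useDnabert && useDnabert2
  branches <- list()
  if (useDnabert) {
    branches <- c(branches, list(branchConfig(
      dnabertShape, channels, 3L, dropout = 0.6)))
  }
  if (useDnabert2) {
    branches <- c(branches, list(branchConfig(
      dnabert2Shape, channels, 3L, dropout = if (dual) 0.4 else 0.6)))
  }
  config <- list(branches = branches, auxDims = as.integer(auxDims),
                 fcUnits = as.integer(fcUnits), headDropout = 0.2,
                 nOutputs = as.integer(nOutputs), reduce = reduce)
  newExpressionCNN(config, seed)
}

#' Build the four-branch model for 50-kb inputs
#'
#' Four embedding matrices enter four branches: the +/-10-kb window embedded
#' by each backend (kernel 3, dropout 0.6) and the +/-25-kb window embedded by
#' each backend (kernel 5, dropout 0.9). Topology and head are otherwise
#' identical to [buildModel10500()].
#'
#' @param auxDims,nOutputs,channels,fcUnits,reduce,seed as in
#'   [buildModel10500()].
#' @param shapes list of four `(n_fragments, dim)` branch input shapes, in the
#'   order (10-kb k-mer-chunk, 10-kb bp-window, 25-kb k-mer-chunk, 25-kb
#'   bp-window); defaults are the canonical fragment counts 40, 37, 100, 97
#'   at width 768.
#' @return an [ExpressionCNN-class].
#' @export
buildModel50000 <- function(auxDims = integer(0), nOutputs = 1L,
                            shapes = list(c(40L, 768L), c(37L, 768L),
                                          c(100L, 768L), c(97L, 768L)),
                            channels = 64L, fcUnits = 64L,
                            reduce = c("max", "mean"), seed = NULL) {
  reduce <- match.arg(reduce)
  if (length(shapes) != 4L) {
    stop(sprintf("the 50-kb model takes exactly 4 branch inputs, got %d",
                 length(shapes)))
  }
  kernels <- c(3L, 3L, 5L, 5L)
  drops <- c(0.6, 0.6, 0.9, 0.9)
  branches <- lapply(seq_len(4L), function(i) {
    branchConfig(shapes[[i]], channels, kernels[i], drops[i])
  })
  config <- list(branches = branches, auxDims = as.integer(auxDims),
                 fcUnits = as.integer(fcUnits), headDropout = 0.2,
                 nOutputs = as.integer(nOutputs), reduce = reduce)
  newExpressionCNN(config, seed)
}

#' Forward pass of an ExpressionCNN
#'
#' Runs the model in eval mode (batch norm uses running statistics, dropout is
#' off), so repeated calls on the same batch return identical predictions.
#'
#' @param model an [ExpressionCNN-class].
#' @param batch list with `branches` (list of `[B x n_fragments x dim]`
#'   arrays, one per branch) and optional `aux` (`[B x sum(auxDims)]` matrix).
#' @return numeric `[B x nOutputs]` prediction matrix.
#' @export
predictExpression <- function(model, batch) {
  stopifnot(is(model, "ExpressionCNN"))
  out <- nnForward(model@config, model@params, model@state$bn, batch,
                   training = FALSE)
  pred <- out$pred
  # models that were trained on standardized labels carry the inverse
  # transform in their state
  if (!is.null(model@state$labelCenter)) {
    pred <- sweep(sweep(pred, 2L, model@state$labelScale, "*"),
                  2L, model@state$labelCenter, "+")
  }
  if (!all(is.finite(pred))) stop("non-finite predictions")
  pred
}

#' Architecture accessors
#'
#' @param model an [ExpressionCNN-class].
#' @return `kernelSizes`/`dropoutRates` return per-branch vectors
#'   (`dropoutRates` appends the head rate); `parameterCount` returns the
#'   total trainable parameter count, or the per-branch count
#'   (conv weights + conv bias + batch-norm scale and shift) when `branch`
#'   is given.
#' @name architecture-accessors
NULL

#' @rdname architecture-accessors
#' @export
kernelSizes <- function(model) {
  vapply(model@config$branches, `[[`, 0L, "kernel")
}

#' @rdname architecture-accessors
#' @export
dropoutRates <- function(model) {
  c(vapply(model@config$branches, `[[`, 0, "dropout"),
    head = model@config$headDropout)
}

#' @rdname architecture-accessors
#' @param branch optional branch index.
#' @export
parameterCount <- function(model, branch = NULL) {
  if (!is.null(branch)) {
    key <- sprintf("br%d", as.integer(branch))
    nm <- grep(paste0("^", key, "\\."), names(model@params), value = TRUE)
    return(sum(vapply(model@params[nm], length, 0L)))
  }
  sum(vapply(model@params, length, 0L))
}

setMethod("show", "ExpressionCNN", function(object) {
  cfg <- object@config
  cat(sprintf("ExpressionCNN: %d branch(es), %d aux feature(s), %d output(s)\n",
              length(cfg$branches), sum(cfg$auxDims), cfg$nOutputs))
  for (i in seq_along(cfg$branches)) {
    br <- cfg$branches[[i]]
    cat(sprintf(
      "  branch %d: [%d x %d] -> conv(%d ch, k=%d) -> BN -> GELU -> drop %.1f -> %s\n",
      i, br$nFragments, br$dim, br$channels, br$kernel, br$dropout, cfg$reduce))
  }
  cat(sprintf("  head: fc(%d) -> BN -> GELU -> drop %.1f -> linear(%d)\n",
              cfg$fcUnits, cfg$headDropout, cfg$nOutputs))
  cat(sprintf("  trainable parameters: %d\n", parameterCount(object)))
})
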