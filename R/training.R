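#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of `yTrue`. At most 1; unbounded below. A constant `yTrue` leaves the
#' metric undefined and is an error.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return a single numeric value.
#' @export
rSquared <- function(yTrue, yPred) {
  yTrue <- as.numeric(yTrue); yPred <- as.numeric(yPred)
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 2L) stop("need at least 2 observations")
  ssTot <- sum((yTrue - mean(yTrue))^2)
  if (ssTot == 0) stop("R-squared is undefined for constant yTrue")
  1 - sum((yTrue - yPred)^2) / ssTot
}

#' Training configuration
#'
#' Defaults follow the reference optimization recipe: batches of 128, Adam
#' with an initial learning rate of 0.002 stepped down to 0.0002 after epoch
#' 10, early stopping on validation performance with a patience of 20 epochs,
#' and 50 total epochs (use 100 for 50-kb inputs).
#'
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param lrInitial learning rate for epochs 1..`lrSwitchEpoch`.
#' @param lrAfter learning rate thereafter.
#' @param lrSwitchEpoch last epoch trained at `lrInitial`.
#' @param patience epochs without validation improvement before stopping;
#'   must not exceed `epochs`.
#' @param seed integer seed controlling the split, weight initialization,
#'   shuffling and dropout.
#' @param split either three fractions `(train, val, test)` summing to 1, or
#'   a list with integer index vectors `train`, `val`, `test`.
#' @return a list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 50L, batchSize = 128L, lrInitial = 0.002,
                        lrAfter = 0.0002, lrSwitchEpoch = 10L, patience = 20L,
                        seed = 1L, split = c(0.8, 0.1, 0.1)) {
  if (is.numeric(split) && length(split) == 3L) {
    if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  } else if (!(is.list(split) &&
               all(c("train", "val", "test") %in% names(split)))) {
    stop("split must be 3 fractions or a list with train/val/test indices")
  }
  if (patience > epochs) stop("patience must not exceed epochs")
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lrInitial = lrInitial, lrAfter = lrAfter,
                 lrSwitchEpoch = as.integer(lrSwitchEpoch),
                 patience = as.integer(patience), seed = as.integer(seed),
                 split = split),
            class = "trainConfig")
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lrInitial` through `lrSwitchEpoch` (default: 0.002 through
#' epoch 10), `lrAfter` from the next epoch on.
#'
#' @param config a [trainConfig()].
#' @param epoch epoch number (1-based).
#' @return the learning rate.
#' @export
lrAtEpoch <- function(config, epoch) {
  stopifnot(epoch >= 1)
  if (epoch <= config$lrSwitchEpoch) config$lrInitial else config$lrAfter
}

#' Assemble model input bundles from a gene table
#'
#' Builds the per-branch embedding arrays plus fused auxiliary features and
#' labels for every gene, either by loading matrices from an embedding cache
#' or by computing them on the fly with the supplied backends.
#'
#' @param geneTable a [GeneTable-class].
#' @param branchSpecs list of branch descriptors, each a list with `backend`
#'   (an [EmbedderBackend-class], or a backend name when loading from cache)
#'   and optional `window` (window set name, default: first set).
#' @param cache embedding cache path, or NULL to embed in memory.
#' @param features character subset of `c("halflife", "tf")` to fuse as
#'   auxiliary inputs.
#' @param labelColumns optional label column names or indices to keep.
#' @return list with `branches` (list of `[n x F x D]` arrays), `aux`
#'   (matrix or NULL), `auxDims`, `labels` (matrix) and `geneId`.
#' @export
assembleBundles <- function(geneTable, branchSpecs, cache = NULL,
                            features = character(0), labelColumns = NULL) {
  stopifnot(is(geneTable, "GeneTable"))
  ids <- geneIds(geneTable)
  branches <- lapply(branchSpecs, function(spec) {
    mats <- if (!is.null(cache)) {
      lapply(ids, function(g) embeddingMatrix(cacheLoad(cache, g, spec$backend)))
    } else {
      be <- spec$backend
      if (!is(be, "EmbedderBackend")) {
        stop("without a cache, branchSpecs must carry EmbedderBackend objects")
      }
      seqs <- windowSequences(geneTable, spec$window)
      lapply(seq_along(ids), function(i) {
        embeddingMatrix(sequenceEmbedding(be, seqs[i], geneId = ids[i]))
      })
    }
    d <- dim(mats[[1L]])
    arr <- array(0, c(length(ids), d[1L], d[2L]))
    for (i in seq_along(mats)) {
      if (!identical(dim(mats[[i]]), d)) {
        stop("inconsistent embedding shape for gene ", ids[i])
      }
      arr[i, , ] <- mats[[i]]
    }
    arr
  })
  aux <- NULL
  auxDims <- integer(0)
  if ("halflife" %in% features) {
    if (is.null(halfLife(geneTable))) stop("gene table has no half-life features")
    aux <- cbind(aux, halfLife(geneTable))
    auxDims <- c(auxDims, 8L)
  }
  if ("tf" %in% features) {
    if (is.null(tfTargets(geneTable))) stop("gene table has no TF features")
    aux <- cbind(aux, tfTargets(geneTable))
    auxDims <- c(auxDims, 181L)
  }
  labels <- expressionLabels(geneTable)
  if (!is.null(labelColumns)) {
    if (is.character(labelColumns) &&
        !all(labelColumns %in% colnames(labels))) {
      stop("unknown label column(s): ",
           paste(setdiff(labelColumns, colnames(labels)), collapse = ", "))
    }
    if (is.numeric(labelColumns) && any(labelColumns > ncol(labels))) {
      stop("label column index out of range")
    }
    labels <- labels[, labelColumns, drop = FALSE]
  }
  list(branches = branches, aux = aux, auxDims = auxDims,
       labels = labels, geneId = ids)
}

bundleSlice <- function(data, idx) {
  aux <- data[["aux"]]   # exact match: 'aux' may be absent, 'auxDims' is not
  list(branches = lapply(data$branches,
                         function(a) a[idx, , , drop = FALSE]),
       aux = if (!is.null(aux)) aux[idx, , drop = FALSE])
}

resolveSplit <- function(split, n) {
  if (is.list(split)) {
    idx <- split[c("train", "val", "test")]
    all <- unlist(idx)
    if (anyDuplicated(all)) stop("split index lists must be disjoint")
    return(idx)
  }
  perm <- sample.int(n)
  nTrain <- floor(split[1L] * n)
  nVal <- floor(split[2L] * n)
  list(train = perm[seq_len(nTrain)],
       val = perm[nTrain + seq_len(nVal)],
       test = perm[(nTrain + nVal + 1L):n])
}

evalR2 <- function(labels, pred) {
  mean(vapply(seq_len(ncol(labels)), function(j) {
    rSquared(labels[, j], pred[, j])
  }, 0))
}

#' Train an ExpressionCNN
#'
#' Minimizes mean-squared error with Adam under the step learning-rate
#' schedule, monitors validation MSE for early stopping (patience epochs
#' without improvement), and restores the best-validation weights before
#' evaluating on the held-out test split. All randomness (split, shuffling,
#' dropout) derives from `config$seed`; identical seeds give identical
#' histories.
#'
#' @param model an [ExpressionCNN-class] (its initial weights are the
#'   starting point).
#' @param data bundles from [assembleBundles()].
#' @param config a [trainConfig()].
#' @return list with `model` (trained, best-validation weights), `history`
#'   (one row per trained epoch: lr, train/val loss, val R-squared) and
#'   `report` (test R-squared, test loss, best epoch).
#' @export
trainModel <- function(model, data, config = trainConfig()) {
  stopifnot(is(model, "ExpressionCNN"))
  n <- nrow(data$labels)
  set.seed(config$seed)
  idx <- resolveSplit(config$split, n)
  config$splitIndices <- idx

  params <- model@params
  bnState <- model@state$bn
  cfg <- model@config
  opt <- adamInit(params)

  # Labels are standardized internally with train-split moments so the
  # optimizer never has to chase an arbitrary label offset/scale; predictions
  # are mapped back before evaluation, leaving R-squared untouched. History
  # losses are reported in standardized label units.
  yTrainRaw <- data$labels[idx$train, , drop = FALSE]
  muY <- colMeans(yTrainRaw)
  sdY <- apply(yTrainRaw, 2L, stats::sd)
  sdY[sdY == 0] <- 1
  scaleY <- function(y) sweep(sweep(y, 2L, muY), 2L, sdY, "/")
  unscaleY <- function(p) sweep(sweep(p, 2L, sdY, "*"), 2L, muY, "+")
  yScaled <- scaleY(data$labels)

  yVal <- data$labels[idx$val, , drop = FALSE]
  yValScaled <- yScaled[idx$val, , drop = FALSE]
  valBatch <- bundleSlice(data, idx$val)

  best <- list(loss = Inf, params = params, bnState = bnState, epoch = 0L)
  sincBest <- 0L
  hist <- vector("list", config$epochs)
  nEpochs <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- lrAtEpoch(config, epoch)
    perm <- idx$train[sample.int(length(idx$train))]
    losses <- c()
    for (bStart in seq.int(1L, length(perm), by = config$batchSize)) {
      bIdx <- perm[bStart:min(bStart + config$batchSize - 1L, length(perm))]
      batch <- bundleSlice(data, bIdx)
      y <- yScaled[bIdx, , drop = FALSE]
      fw <- nnForward(cfg, params, bnState, batch, training = TRUE)
      bnState <- fw$bnState
      resid <- fw$pred - y
      losses <- c(losses, mean(resid^2))
      dPred <- 2 * resid / length(resid)
      grads <- nnBackward(cfg, params, fw$caches, dPred)
      stepOut <- adamStep(params, grads, opt, lr)
      params <- stepOut$params
      opt <- stepOut$opt
    }
    valPred <- nnForward(cfg, params, bnState, valBatch, training = FALSE)$pred
    valLoss <- mean((valPred - yValScaled)^2)
    valR2 <- evalR2(yVal, unscaleY(valPred))
    nEpochs <- epoch
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                trainLoss = mean(losses),
                                valLoss = valLoss, valR2 = valR2)
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, params = params, bnState = bnState,
                   epoch = epoch)
      sincBest <- 0L
    } else {
      sincBest <- sincBest + 1L
      if (sincBest >= config$patience) break
    }
  }

  trained <- new("ExpressionCNN", config = cfg, params = best$params,
                 state = list(bn = best$bnState,
                              labelCenter = muY, labelScale = sdY))
  testBatch <- bundleSlice(data, idx$test)
  yTest <- data$labels[idx$test, , drop = FALSE]
  testPred <- predictExpression(trained, testBatch)
  list(model = trained,
       history = do.call(rbind, hist[seq_len(nEpochs)]),
       report = list(testR2 = evalR2(yTest, testPred),
                     testLoss = mean((testPred - yTest)^2),
                     bestEpoch = best$epoch,
                     bestValLoss = best$loss,
                     split = idx))
}

#' K-fold partition of gene indices
#'
#' Disjoint folds covering all `n` indices, with sizes differing by at most
#' one; deterministic for a fixed seed.
#'
#' @param n number of genes (must be >= k).
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return list of `k` integer index vectors.
#' @export
kfold <- function(n, k = 10L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < k) stop(sprintf("cannot split %d genes into %d folds", n, k))
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}
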