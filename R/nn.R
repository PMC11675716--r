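## Internal neural-network primitives for the expression CNN.
##
## The network is small and its shape is fixed by the architecture config, so
## forward and backward passes are written directly against base-R matrix
## algebra. Conventions:
##   - branch inputs are arrays [B x F x D] (batch, fragments, embedding dim);
##   - convolution is 1-D over the fragment axis with D input channels and
##     'same' zero padding (odd kernels), weights stored as a (k*D) x C matrix
##     whose rows are ordered offset-major;
##   - batch norm normalizes per channel over (batch x positions) for conv
##     activations and per feature over the batch for dense activations;
##   - GELU is the exact Phi-based form x * pnorm(x);
##   - dropout is inverted (mask / (1 - p)) and active only in training mode.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

gelu <- function(x) x * stats::pnorm(x)
geluGrad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

rowBroadcast <- function(m, v) m * rep(v, each = nrow(m))

## X: [B x F x D] -> column matrix [B*F x k*D], rows indexed (batch fastest).
im2col <- function(X, kernel) {
  d <- dim(X)
  B <- d[1L]; F <- d[2L]; D <- d[3L]
  pad <- (kernel - 1L) %/% 2L
  Xp <- array(0, c(B, F + 2L * pad, D))
  Xp[, pad + seq_len(F), ] <- X
  out <- matrix(0, B * F, kernel * D)
  for (o in seq_len(kernel)) {
    out[, (o - 1L) * D + seq_len(D)] <-
      matrix(Xp[, o:(o + F - 1L), , drop = FALSE], B * F, D)
  }
  out
}

bnForward <- function(x, gamma, beta, running, training) {
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = nrow(x))
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + BN_EPS)
    xhat <- rowBroadcast(xc, invstd)
    running$mean <- (1 - BN_MOMENTUM) * running$mean + BN_MOMENTUM * mu
    running$var <- (1 - BN_MOMENTUM) * running$var + BN_MOMENTUM * v
    list(out = rowBroadcast(xhat, gamma) + rep(beta, each = nrow(x)),
         cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
         running = running)
  } else {
    invstd <- 1 / sqrt(running$var + BN_EPS)
    xhat <- rowBroadcast(x - rep(running$mean, each = nrow(x)), invstd)
    list(out = rowBroadcast(xhat, gamma) + rep(beta, each = nrow(x)),
         cache = NULL, running = running)
  }
}

bnBackward <- function(dout, cache) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- rowBroadcast(dout, cache$gamma)
  dx <- rowBroadcast(
    dxhat - rep(colMeans(dxhat), each = n) -
      xhat * rep(colMeans(dxhat * xhat), each = n),
    cache$invstd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## Global max over the fragment axis. A: [B x F x C] -> list(out [B x C], idx).
reduceMaxForward <- function(A) {
  d <- dim(A)
  B <- d[1L]; F <- d[2L]; C <- d[3L]
  m <- matrix(aperm(A, c(2L, 1L, 3L)), F, B * C)   # F x (B*C)
  tm <- t(m)                                       # (B*C) x F
  j <- max.col(tm, ties.method = "first")
  vals <- tm[cbind(seq_len(B * C), j)]
  list(out = matrix(vals, B, C), idx = j, dims = d)
}

reduceMaxBackward <- function(dH, idx, dims) {
  B <- dims[1L]; F <- dims[2L]; C <- dims[3L]
  dm <- matrix(0, F, B * C)
  dm[cbind(idx, seq_len(B * C))] <- as.vector(dH)
  aperm(array(dm, c(F, B, C)), c(2L, 1L, 3L))
}

## Mean over the fragment axis (alternative reduction, config$reduce = "mean").
reduceMeanForward <- function(A) {
  d <- dim(A)
  m <- matrix(aperm(A, c(2L, 1L, 3L)), d[2L], d[1L] * d[3L])
  list(out = matrix(colMeans(m), d[1L], d[3L]), idx = NULL, dims = d)
}

reduceMeanBackward <- function(dH, dims) {
  B <- dims[1L]; F <- dims[2L]; C <- dims[3L]
  dm <- matrix(rep(as.vector(dH) / F, each = F), F, B * C)
  aperm(array(dm, c(F, B, C)), c(2L, 1L, 3L))
}

dropoutForward <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(out = x * mask, mask = mask)
}

initParams <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  params <- list()
  for (i in seq_along(config$branches)) {
    br <- config$branches[[i]]
    fanIn <- br$kernel * br$dim
    params[[sprintf("br%d.W", i)]] <-
      matrix(stats::rnorm(fanIn * br$channels, sd = sqrt(2 / fanIn)),
             fanIn, br$channels)
    params[[sprintf("br%d.b", i)]] <- numeric(br$channels)
    params[[sprintf("br%d.gamma", i)]] <- rep(1, br$channels)
    params[[sprintf("br%d.beta", i)]] <- numeric(br$channels)
  }
  inDim <- sum(vapply(config$branches, `[[`, 0L, "channels")) +
    sum(config$auxDims)
  params[["head.W1"]] <-
    matrix(stats::rnorm(inDim * config$fcUnits, sd = sqrt(2 / inDim)),
           inDim, config$fcUnits)
  params[["head.b1"]] <- numeric(config$fcUnits)
  params[["head.gamma"]] <- rep(1, config$fcUnits)
  params[["head.beta"]] <- numeric(config$fcUnits)
  params[["head.W2"]] <-
    matrix(stats::rnorm(config$fcUnits * config$nOutputs,
                        sd = sqrt(1 / config$fcUnits)),
           config$fcUnits, config$nOutputs)
  params[["head.b2"]] <- numeric(config$nOutputs)
  params
}

initBnState <- function(config) {
  st <- list()
  for (i in seq_along(config$branches)) {
    C <- config$branches[[i]]$channels
    st[[sprintf("br%d", i)]] <- list(mean = numeric(C), var = rep(1, C))
  }
  st[["head"]] <- list(mean = numeric(config$fcUnits),
                       var = rep(1, config$fcUnits))
  st
}

checkBatchShapes <- function(config, batch) {
  nb <- length(config$branches)
  if (length(batch$branches) != nb) {
    stop(sprintf("model expects %d branch input(s), got %d",
                 nb, length(batch$branches)))
  }
  for (i in seq_len(nb)) {
    d <- dim(batch$branches[[i]])
    br <- config$branches[[i]]
    if (length(d) != 3L || d[2L] != br$nFragments || d[3L] != br$dim) {
      stop(sprintf(
        "branch %d input shape [%s] does not match expected [B x %d x %d]",
        i, paste(d, collapse = " x "), br$nFragments, br$dim))
    }
  }
  auxTotal <- sum(config$auxDims)
  auxGot <- if (is.null(batch$aux)) 0L else ncol(batch$aux)
  if (auxGot != auxTotal) {
    stop(sprintf("expected %d auxiliary feature(s), got %d", auxTotal, auxGot))
  }
  invisible(TRUE)
}

## Full forward pass. Returns predictions plus (in training mode) the caches
## and updated batch-norm running state needed for the backward pass.
nnForward <- function(config, params, bnState, batch, training = FALSE) {
  checkBatchShapes(config, batch)
  B <- dim(batch$branches[[1L]])[1L]
  caches <- list(branches = vector("list", length(config$branches)))
  H <- vector("list", length(config$branches))
  for (i in seq_along(config$branches)) {
    br <- config$branches[[i]]
    key <- sprintf("br%d", i)
    Xcol <- im2col(batch$branches[[i]], br$kernel)
    Y <- Xcol %*% params[[paste0(key, ".W")]] +
      rep(params[[paste0(key, ".b")]], each = B * br$nFragments)
    bn <- bnForward(Y, params[[paste0(key, ".gamma")]],
                    params[[paste0(key, ".beta")]], bnState[[key]], training)
    bnState[[key]] <- bn$running
    act <- gelu(bn$out)
    drop <- dropoutForward(act, br$dropout, training)
    A <- array(drop$out, c(B, br$nFragments, br$channels))
    red <- if (identical(config$reduce, "mean")) reduceMeanForward(A)
           else reduceMaxForward(A)
    H[[i]] <- red$out
    caches$branches[[i]] <- list(Xcol = Xcol, bn = bn$cache, preAct = bn$out,
                                 mask = drop$mask, idx = red$idx,
                                 dims = c(B, br$nFragments, br$channels))
  }
  Z0 <- do.call(cbind, H)
  if (!is.null(batch$aux) && ncol(batch$aux) > 0L) Z0 <- cbind(Z0, batch$aux)
  U <- Z0 %*% params[["head.W1"]] + rep(params[["head.b1"]], each = B)
  bnH <- bnForward(U, params[["head.gamma"]], params[["head.beta"]],
                   bnState[["head"]], training)
  bnState[["head"]] <- bnH$running
  actH <- gelu(bnH$out)
  dropH <- dropoutForward(actH, config$headDropout, training)
  pred <- dropH$out %*% params[["head.W2"]] +
    rep(params[["head.b2"]], each = B)
  caches$head <- list(Z0 = Z0, bn = bnH$cache, preAct = bnH$out,
                      mask = dropH$mask, hidden = dropH$out)
  list(pred = pred, caches = if (training) caches, bnState = bnState)
}

## Backward pass from dPred; returns gradients named like params.
nnBackward <- function(config, params, caches, dPred) {
  grads <- list()
  ch <- caches$head
  grads[["head.W2"]] <- t(ch$hidden) %*% dPred
  grads[["head.b2"]] <- colSums(dPred)
  dHidden <- dPred %*% t(params[["head.W2"]])
  if (!is.null(ch$mask)) dHidden <- dHidden * ch$mask
  dBnOut <- dHidden * geluGrad(ch$preAct)
  bb <- bnBackward(dBnOut, ch$bn)
  grads[["head.gamma"]] <- bb$dgamma
  grads[["head.beta"]] <- bb$dbeta
  dU <- bb$dx
  grads[["head.W1"]] <- t(ch$Z0) %*% dU
  grads[["head.b1"]] <- colSums(dU)
  dZ0 <- dU %*% t(params[["head.W1"]])

  col <- 0L
  for (i in seq_along(config$branches)) {
    br <- config$branches[[i]]
    key <- sprintf("br%d", i)
    cb <- caches$branches[[i]]
    dH <- dZ0[, col + seq_len(br$channels), drop = FALSE]
    col <- col + br$channels
    dA <- if (identical(config$reduce, "mean")) reduceMeanBackward(dH, cb$dims)
          else reduceMaxBackward(dH, cb$idx, cb$dims)
    dAct <- matrix(dA, prod(cb$dims[1:2]), cb$dims[3L])
    if (!is.null(cb$mask)) dAct <- dAct * cb$mask
    dY <- dAct * geluGrad(cb$preAct)
    bbB <- bnBackward(dY, cb$bn)
    grads[[paste0(key, ".gamma")]] <- bbB$dgamma
    grads[[paste0(key, ".beta")]] <- bbB$dbeta
    grads[[paste0(key, ".W")]] <- t(cb$Xcol) %*% bbB$dx
    grads[[paste0(key, ".b")]] <- colSums(bbB$dx)
    # input gradients are not propagated: embeddings are fixed features
  }
  grads
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, opt, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}
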