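# Internal 1-D convolutional network engine.
#
# No deep-learning framework is involved: the forward and backward passes
# are built from BLAS matrix products plus the compiled data-movement
# kernels in src/nn_kernels.cpp. A minibatch of B windows with C channels
# and L samples is laid out as a C x (L*B) matrix whose columns are grouped
# per window, so a 1x3 "same" convolution becomes one GEMM against a
# 3C-row shifted-copy matrix (im2col), and 1x2 max-pooling acts on the
# odd/even column interleave. The conv backward pass rebuilds the im2col
# matrix instead of caching it, trading a little compute for memory.

# Compile a ModelSpec into the flat layer list the passes iterate over.
# Conv/FC layers get Xavier-uniform weights and zero biases.
initLayers <- function(spec, seed) {
  xavier <- function(nr, nc, fanIn, fanOut) {
    lim <- sqrt(6 / (fanIn + fanOut))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  withSeed(seed, {
    layers <- list()
    Cin <- spec@inputChannels
    L <- spec@inputLength
    for (stage in spec@stageWidths) {
      for (Cout in stage) {
        layers[[length(layers) + 1L]] <- list(
          type = "conv",
          W = xavier(Cout, 3L * Cin, 3L * Cin, 3L * Cout),
          b = numeric(Cout), Cin = Cin)
        layers[[length(layers) + 1L]] <- list(type = "relu")
        Cin <- Cout
      }
      layers[[length(layers) + 1L]] <- list(type = "pool")
      L <- L %/% 2L
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten", C = Cin, L = L)
    nIn <- Cin * L
    for (nOut in spec@fcWidths) {
      layers[[length(layers) + 1L]] <- list(
        type = "fc", W = xavier(nOut, nIn, nIn, nOut), b = numeric(nOut))
      layers[[length(layers) + 1L]] <- list(type = "relu")
      layers[[length(layers) + 1L]] <- list(type = "dropout",
                                            p = spec@dropoutP)
      nIn <- nOut
    }
    layers[[length(layers) + 1L]] <- list(
      type = "fc", W = xavier(1L, nIn, nIn, 1L), b = numeric(1L))
    layers
  })
}

# Forward pass. X is C x (L*B); returns predictions (length B) and, when
# `train` is TRUE, the caches the backward pass needs. Dropout draws from
# the current RNG stream only in training mode.
netForward <- function(layers, X, B, inputLength, train = FALSE) {
  L <- inputLength
  caches <- if (train) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    switch(ly$type,
      conv = {
        Xin <- X
        X <- .conv1dFwd(X, ly$W, ly$b, L)
        if (train) caches[[i]] <- list(X = Xin, L = L)
      },
      relu = {
        mask <- X > 0
        X <- X * mask
        if (train) caches[[i]] <- list(mask = mask)
      },
      pool = {
        pf <- .poolFwd(X)
        if (train) caches[[i]] <- list(takeFirst = pf$takeFirst)
        X <- pf$Y
        L <- L %/% 2L
      },
      flatten = {
        X <- matrix(X, nrow = ly$C * ly$L)
      },
      fc = {
        if (train) caches[[i]] <- list(X = X)
        X <- ly$W %*% X + ly$b
      },
      dropout = {
        if (train && ly$p > 0) {
          mask <- (matrix(stats::runif(length(X)), nrow(X)) >= ly$p) /
            (1 - ly$p)
          X <- X * mask
          caches[[i]] <- list(mask = mask)
        }
      })
  }
  list(pred = as.numeric(X), caches = caches)
}

# Backward pass from d(loss)/d(pred); returns per-layer gradients (NULL for
# parameter-free layers).
netBackward <- function(layers, caches, dPred, B) {
  grads <- vector("list", length(layers))
  dX <- matrix(dPred, nrow = 1L)
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- caches[[i]]
    switch(ly$type,
      conv = {
        bw <- .conv1dBwd(cc$X, ly$W, dX, cc$L)
        grads[[i]] <- list(W = bw$dW, b = as.numeric(bw$db))
        dX <- bw$dX
      },
      relu = {
        dX <- dX * cc$mask
      },
      pool = {
        dX <- .poolBwd(dX, cc$takeFirst)
      },
      flatten = {
        dX <- matrix(dX, nrow = ly$C)
      },
      fc = {
        grads[[i]] <- list(W = tcrossprod(dX, cc$X), b = rowSums(dX))
        dX <- crossprod(ly$W, dX)
      },
      dropout = {
        if (!is.null(cc)) dX <- dX * cc$mask
      })
  }
  grads
}

# Adam optimizer state and update, keyed to the layer list.
adamInit <- function(layers) {
  lapply(layers, function(ly)
    if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                             mb = ly$b * 0, vb = ly$b * 0))
}

adamStep <- function(layers, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

# Mean-squared-error cost of a layer stack over windows laid out as
# C x (L*n); evaluated in slices to bound memory.
netCost <- function(layers, X, y, inputLength, sliceB = 256L) {
  n <- length(y)
  L <- inputLength
  se <- 0
  at <- 1L
  while (at <= n) {
    hi <- min(n, at + sliceB - 1L)
    cols <- ((at - 1L) * L + 1L):(hi * L)
    out <- netForward(layers, X[, cols, drop = FALSE], hi - at + 1L, L)
    se <- se + sum((out$pred - y[at:hi])^2)
    at <- hi + 1L
  }
  se / n
}

# Predictions for windows laid out as C x (L*n).
netPredict <- function(layers, X, n, inputLength, sliceB = 256L) {
  L <- inputLength
  preds <- numeric(n)
  at <- 1L
  while (at <= n) {
    hi <- min(n, at + sliceB - 1L)
    cols <- ((at - 1L) * L + 1L):(hi * L)
    out <- netForward(layers, X[, cols, drop = FALSE], hi - at + 1L, L)
    preds[at:hi] <- out$pred
    at <- hi + 1L
  }
  preds
}

# Window tensor (n x C x L) -> the engine's C x (L*n) layout.
flattenWindows <- function(arr) {
  d <- dim(arr)
  X <- aperm(arr, c(2L, 3L, 1L))
  dim(X) <- c(d[2], d[3] * d[1])
  X
}

# Core training loop: Adam on L2 loss with per-epoch validation cost and
# best-epoch checkpointing. Returns layers at the best epoch plus history.
fitLayers <- function(layers, xTrain, yTrain, xVal, yVal, spec, hyper) {
  L <- spec@inputLength
  nTr <- length(yTrain)
  state <- adamInit(layers)
  if (hyper@centerOutputBias) {
    out <- length(layers)
    layers[[out]]$b <- mean(yTrain)
  }
  history <- data.frame(epoch = seq_len(hyper@epochs),
                        trainCost = NA_real_, valCost = NA_real_)
  best <- list(cost = Inf, layers = layers, epoch = 0L)
  t <- 0L
  withSeed(deriveSeed(hyper@seed, 101L), {
    for (epoch in seq_len(hyper@epochs)) {
      ord <- sample.int(nTr)
      at <- 1L
      costAcc <- 0
      nb <- 0L
      while (at <= nTr) {
        bi <- ord[at:min(nTr, at + hyper@batchSize - 1L)]
        B <- length(bi)
        cols <- as.vector(outer(seq_len(L), (bi - 1L) * L, `+`))
        Xb <- xTrain[, cols, drop = FALSE]
        yb <- yTrain[bi]
        fwd <- netForward(layers, Xb, B, L, train = TRUE)
        resid <- fwd$pred - yb
        cost <- mean(resid^2)
        if (!is.finite(cost))
          stop(sprintf("non-finite loss at epoch %d", epoch))
        grads <- netBackward(layers, fwd$caches, 2 * resid / B, B)
        t <- t + 1L
        upd <- adamStep(layers, grads, state, hyper@learningRate, t)
        layers <- upd$layers
        state <- upd$state
        costAcc <- costAcc + cost
        nb <- nb + 1L
        at <- at + hyper@batchSize
      }
      history$trainCost[epoch] <- costAcc / nb
      history$valCost[epoch] <- netCost(layers, xVal, yVal, L)
      if (history$valCost[epoch] < best$cost) {
        best <- list(cost = history$valCost[epoch], layers = layers,
                     epoch = epoch)
      }
    }
  })
  list(layers = best$layers, history = history, bestEpoch = best$epoch)
}
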