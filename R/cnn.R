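#' Classification head configuration
#'
#' The trainable head placed on top of the frozen backbone: batch
#' normalization of the pooled features, dropout, `nHiddenLayers` fully
#' connected ReLU layers (0 means a single linear map straight to the output)
#' and a sigmoid output unit. Defaults are the tuned values for this task:
#' no hidden layer and dropout 0.5.
#'
#' @param nHiddenLayers Number of hidden layers, 0, 1 or 2.
#' @param nNeurons Neurons per hidden layer (ignored when `nHiddenLayers = 0`).
#' @param dropout Dropout probability in `[0, 1)`.
#' @return A list of class `"HeadConfig"`.
#' @export
headConfig <- function(nHiddenLayers = 0L, nNeurons = 32L, dropout = 0.5) {
  stopifnot(nHiddenLayers %in% 0:2, nNeurons >= 1, dropout >= 0, dropout < 1)
  structure(list(nHiddenLayers = as.integer(nHiddenLayers),
                 nNeurons = as.integer(nNeurons), dropout = dropout),
            class = "HeadConfig")
}

#' Training configuration
#'
#' Optimization settings for the head: Adam on the binary log-loss for a fixed
#' number of epochs, with L2 weight decay. Defaults are the tuned values:
#' learning rate 0.001, weight decay 0.01, 20 epochs, batch size 16.
#'
#' @param learningRate Adam step size, `> 0` (0 is allowed and leaves the
#'   parameters untouched, useful for diagnostics).
#' @param weightDecay L2 penalty coefficient on the dense-layer weights.
#' @param epochs Number of passes over the training data, `>= 1`.
#' @param batchSize Minibatch size.
#' @param seed Seed controlling weight initialization, batch shuffling and
#'   dropout masks.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(learningRate = 0.001, weightDecay = 0.01,
                        epochs = 20L, batchSize = 16L, seed = 1L) {
  stopifnot(learningRate >= 0, weightDecay >= 0, epochs >= 1, batchSize >= 1)
  structure(list(learningRate = learningRate, weightDecay = weightDecay,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 optimizer = "adam", loss = "binary_log_loss",
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Build an untrained transfer-learning model
#'
#' Attaches a trainable head (see [headConfig()]) to a frozen backbone. The
#' backbone's parameters are never modified by [trainModel()]; only the head
#' (batch-norm affine parameters and dense layers) is optimized.
#'
#' @param backbone A `"Backbone"` object, e.g. [tinyBackbone()], or a backbone
#'   identifier accepted by [getBackbone()].
#' @param head A [headConfig()].
#' @return A list of class `"CnnModel"` (untrained; see [trainModel()]).
#' @export
buildModel <- function(backbone = tinyBackbone(), head = headConfig()) {
  if (is.character(backbone)) backbone <- getBackbone(backbone)
  stopifnot(inherits(backbone, "Backbone"), inherits(head, "HeadConfig"))
  structure(list(backbone = backbone, head = head, params = NULL,
                 lossTrace = numeric(0), trained = FALSE),
            class = "CnnModel")
}

# Layer sizes of the head: featureDim -> hidden... -> 1.
headLayerSizes <- function(featureDim, head) {
  c(featureDim, rep(head$nNeurons, head$nHiddenLayers), 1L)
}

initHeadParams <- function(featureDim, head) {
  sizes <- headLayerSizes(featureDim, head)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(gamma = rep(1, featureDim), beta = numeric(featureDim),
       runMean = numeric(featureDim), runVar = rep(1, featureDim),
       W = W, b = b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass of the head on a feature matrix (n x d). In training mode the
# batch statistics and dropout masks come from the current RNG stream and the
# intermediates needed for backprop are returned.
headForward <- function(X, params, head, training = FALSE, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(sweep(X, 2, mu)^2)
  } else {
    mu <- params$runMean
    va <- params$runVar
  }
  xhat <- sweep(sweep(X, 2, mu), 2, sqrt(va + eps), "/")
  a <- sweep(sweep(xhat, 2, params$gamma, "*"), 2, params$beta, "+")
  masks <- list()
  acts <- list()
  p <- head$dropout
  nl <- length(params$W)
  if (training && p > 0) {
    m <- matrix(stats::rbinom(length(a), 1, 1 - p), nrow(a)) / (1 - p)
    masks[[1]] <- m
    a <- a * m
  }
  acts[[1]] <- a
  for (l in seq_len(nl)) {
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], "+")
    if (l < nl) {
      a <- pmax(z, 0)
      if (training && p > 0) {
        m <- matrix(stats::rbinom(length(a), 1, 1 - p), nrow(a)) / (1 - p)
        masks[[l + 1]] <- m
        a <- a * m
      }
      acts[[l + 1]] <- a
    } else {
      a <- sigmoid(z)
    }
  }
  list(prob = as.numeric(a), xhat = xhat, acts = acts, masks = masks,
       batchMean = mu, batchVar = va)
}

# Backward pass: gradients of mean binary log-loss (+ L2 on dense weights).
headBackward <- function(fw, y, params, head, weightDecay) {
  n <- length(y)
  nl <- length(params$W)
  grads <- list(W = vector("list", nl), b = vector("list", nl))
  delta <- matrix((fw$prob - y) / n, ncol = 1)        # dL/dz_out
  for (l in rev(seq_len(nl))) {
    a <- fw$acts[[l]]
    grads$W[[l]] <- crossprod(a, delta) + weightDecay * params$W[[l]]
    grads$b[[l]] <- colSums(delta)
    if (l > 1) {
      da <- delta %*% t(params$W[[l]])
      if (length(fw$masks) >= l && !is.null(fw$masks[[l]])) {
        da <- da * fw$masks[[l]]
      }
      delta <- da * (fw$acts[[l]] > 0)                # ReLU derivative
    }
  }
  da0 <- delta %*% t(params$W[[1]])
  if (length(fw$masks) >= 1 && !is.null(fw$masks[[1]])) {
    da0 <- da0 * fw$masks[[1]]
  }
  grads$gamma <- colSums(da0 * fw$xhat)
  grads$beta <- colSums(da0)
  grads
}

adamInit <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = zero(params[c("gamma", "beta", "W", "b")]),
       v = zero(params[c("gamma", "beta", "W", "b")]), t = 0L)
}

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^state$t)
    vhat <- v / (1 - b2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (nm in c("gamma", "beta")) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  for (nm in c("W", "b")) {
    for (l in seq_along(params[[nm]])) {
      r <- upd(params[[nm]][[l]], grads[[nm]][[l]],
               state$m[[nm]][[l]], state$v[[nm]][[l]])
      params[[nm]][[l]] <- r$p
      state$m[[nm]][[l]] <- r$m; state$v[[nm]][[l]] <- r$v
    }
  }
  list(params = params, state = state)
}

bceLoss <- function(prob, y, eps = 1e-12) {
  -mean(y * log(prob + eps) + (1 - y) * log(1 - prob + eps))
}

#' Train the head of a transfer-learning model
#'
#' Extracts frozen backbone features from every training image, then optimizes
#' the head with Adam on the binary log-loss for a fixed number of epochs.
#' Dropout, weight decay and batch normalization regularize the fit. The
#' backbone is bit-identical before and after training; all randomness
#' (initialization, shuffling, dropout) is driven by `config$seed`.
#'
#' @param model An untrained (or previously trained) `"CnnModel"` from
#'   [buildModel()].
#' @param images List of [EncodedImage-class] objects or rasters on 0..255.
#' @param labels 0/1 labels; both classes must be present.
#' @param config A [trainConfig()].
#' @return The trained `"CnnModel"`, with `$lossTrace` holding the mean
#'   training log-loss per epoch.
#' @export
trainModel <- function(model, images, labels, config = trainConfig()) {
  stopifnot(inherits(model, "CnnModel"), inherits(config, "TrainConfig"))
  y <- as.numeric(labels)
  if (length(unique(y)) < 2) {
    stop("training labels must contain both classes")
  }
  bb <- model$backbone
  X <- t(vapply(images, function(im) backboneFeatures(bb, im),
                numeric(bb$featureDim)))
  withSeed(config$seed, {
    params <- initHeadParams(bb$featureDim, model$head)
    opt <- adamInit(params)
    n <- nrow(X)
    trace <- numeric(config$epochs)
    for (e in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        fw <- headForward(X[idx, , drop = FALSE], params, model$head,
                          training = TRUE)
        losses[bi] <- bceLoss(fw$prob, y[idx])
        if (config$learningRate > 0) {
          # running statistics for inference (momentum 0.1)
          params$runMean <- 0.9 * params$runMean + 0.1 * fw$batchMean
          params$runVar <- 0.9 * params$runVar + 0.1 * fw$batchVar
          grads <- headBackward(fw, y[idx], params, model$head,
                                config$weightDecay)
          st <- adamStep(params, grads, opt, config$learningRate)
          params <- st$params
          opt <- st$state
        }
      }
      trace[e] <- mean(losses)
    }
    model$params <- params
    model$lossTrace <- trace
    model$trained <- TRUE
    model
  })
}

#' Predict positive-class probabilities
#'
#' Deterministic inference: frozen backbone features, batch normalization with
#' the running statistics, no dropout, sigmoid output.
#'
#' @param model A trained `"CnnModel"`.
#' @param images A single image or a list of images.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predictProb <- function(model, images) {
  stopifnot(inherits(model, "CnnModel"))
  if (!model$trained) stop("model has not been trained")
  if (!is.list(images) || is(images, "EncodedImage")) images <- list(images)
  bb <- model$backbone
  X <- t(vapply(images, function(im) backboneFeatures(bb, im),
                numeric(bb$featureDim)))
  headForward(X, model$params, model$head, training = FALSE)$prob
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's standard serialization (RDS).
#'
#' @param model A `"CnnModel"`.
#' @param path Checkpoint file path.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
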