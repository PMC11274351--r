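# Small helpers: encoded images of two classes with bar widths that separate.
separableImages <- function(n, seed, enc = encodingConfig(80, 60)) {
  withr::with_seed(seed, {
    labels <- rep(c(0L, 1L), each = n / 2)
    imgs <- lapply(seq_len(n), function(i) {
      lo <- if (labels[i] == 1) 0.6 else 0.05
      encodeRecord(runif(9, lo, lo + 0.3), enc)
    })
    list(images = imgs, labels = labels)
  })
}

test_that("unknown backbones are rejected with the available list", {
  expect_error(getBackbone("resnet18"), "tiny")
  expect_true(inherits(tinyBackbone(), "Backbone"))
  expect_identical(tinyBackbone(), tinyBackbone())  # deterministic build
})

test_that("a headless model has one linear map from features to one output", {
  d <- separableImages(8, 1)
  m <- trainModel(buildModel(tinyBackbone(), headConfig(0)),
                  d$images, d$labels, trainConfig(epochs = 1))
  expect_length(m$params$W, 1)
  expect_equal(dim(m$params$W[[1]]), c(tinyBackbone()$featureDim, 1))
  m2 <- trainModel(buildModel(tinyBackbone(), headConfig(2, nNeurons = 8)),
                   d$images, d$labels, trainConfig(epochs = 1))
  expect_length(m2$params$W, 3)
})

test_that("the frozen backbone is bit-identical after training", {
  d <- separableImages(12, 2)
  model <- buildModel(tinyBackbone(), headConfig())
  before <- model$backbone$weights
  fitted <- trainModel(model, d$images, d$labels, trainConfig(epochs = 3))
  expect_identical(fitted$backbone$weights, before)
})

test_that("training reduces the loss on separable classes and probs stay in (0,1)", {
  d <- separableImages(40, 3)
  m <- trainModel(buildModel(tinyBackbone(), headConfig()),
                  d$images, d$labels, trainConfig(epochs = 20, seed = 5))
  expect_lt(m$lossTrace[20], m$lossTrace[1])
  p <- predictProb(m, d$images)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean(p), 0)
  expect_lt(mean(p), 1)
  expect_false(all(p %in% c(0, 1)))
  expect_error(trainModel(buildModel(), d$images, rep(1L, 40), trainConfig()),
               "both classes")
})

test_that("zero learning rate leaves the head unchanged with a flat trace", {
  d <- separableImages(16, 4)
  # dropout 0 and a single full batch make every epoch's loss a
  # deterministic function of the (unchanged) parameters
  m <- trainModel(buildModel(tinyBackbone(), headConfig(dropout = 0)),
                  d$images, d$labels,
                  trainConfig(learningRate = 0, epochs = 5, batchSize = 16,
                              seed = 6))
  expect_equal(m$lossTrace, rep(m$lossTrace[1], 5))
  init <- withr::with_seed(6, {
    tab2img:::initHeadParams(tinyBackbone()$featureDim, headConfig(dropout = 0))
  })
  expect_equal(m$params$W, init$W)
})

test_that("training is deterministic for a fixed seed", {
  d <- separableImages(20, 7)
  cfg <- trainConfig(epochs = 5, seed = 11)
  m1 <- trainModel(buildModel(), d$images, d$labels, cfg)
  m2 <- trainModel(buildModel(), d$images, d$labels, cfg)
  expect_identical(m1$lossTrace, m2$lossTrace)
  expect_identical(m1$params, m2$params)
  expect_identical(predictProb(m1, d$images[1:3]),
                   predictProb(m2, d$images[1:3]))
})

test_that("head gradients match numerical differentiation", {
  withr::with_seed(8, {
    X <- matrix(rnorm(5 * 6), 5, 6)
    y <- c(0, 1, 0, 1, 1)
    head <- headConfig(1, nNeurons = 4, dropout = 0)
    params <- tab2img:::initHeadParams(6, head)
    params$runMean <- colMeans(X)
    params$runVar <- apply(X, 2, function(c) mean((c - mean(c))^2))
  })
  lossAt <- function(p) {
    fw <- tab2img:::headForward(X, p, head, training = FALSE)
    tab2img:::bceLoss(fw$prob, y)
  }
  fw <- tab2img:::headForward(X, params, head, training = FALSE)
  # evaluation-mode forward reuses the stored stats, so analytic gradients
  # from a training=FALSE pass are comparable to finite differences
  gr <- tab2img:::headBackward(fw, y, params, head, weightDecay = 0)
  eps <- 1e-6
  for (l in 1:2) {
    for (idx in sample(length(params$W[[l]]), 3)) {
      p2 <- params; p2$W[[l]][idx] <- p2$W[[l]][idx] + eps
      num <- (lossAt(p2) - lossAt(params)) / eps
      expect_equal(gr$W[[l]][idx], num, tolerance = 1e-3)
    }
  }
  p2 <- params; p2$gamma[2] <- p2$gamma[2] + eps
  expect_equal(gr$gamma[2], (lossAt(p2) - lossAt(params)) / eps,
               tolerance = 1e-3)
})

test_that("held-out AUC reaches 0.9 on separable bars for most seeds", {
  hits <- 0
  for (seed in 1:5) {
    train <- separableImages(40, 100 + seed)
    test <- separableImages(20, 200 + seed)
    m <- trainModel(buildModel(tinyBackbone(), headConfig()),
                    train$images, train$labels,
                    trainConfig(epochs = 20, seed = seed))
    auc <- rocAuc(predictProb(m, test$images), test$labels)$auc
    hits <- hits + (auc >= 0.9)
  }
  expect_gte(hits, 3)
})

test_that("model checkpoints survive a save/load round trip", {
  d <- separableImages(10, 9)
  m <- trainModel(buildModel(), d$images, d$labels, trainConfig(epochs = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_equal(predictProb(m2, d$images[1:2]), predictProb(m, d$images[1:2]))
})
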