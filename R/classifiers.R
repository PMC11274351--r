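#' Probabilistic classifier contract
#'
#' A uniform contract satisfied by the CNN pipeline, the tabular baselines and
#' the ensembles: a `fit` function producing a state and a `predict` function
#' mapping that state and new inputs to positive-class probabilities in
#' `[0, 1]`. Classifiers are *factories* — they are re-fitted from scratch in
#' every cross-validation fold, which is required for honest leave-one-out
#' evaluation.
#'
#' @param name Display name.
#' @param type `"tabular"` (fit receives an `n x m` feature matrix) or
#'   `"image"` (fit receives a list of rasters).
#' @param fit `function(x, y, seed)` returning an opaque fitted state.
#' @param predict `function(state, x)` returning probabilities.
#' @return A list of class `"ProbabilisticClassifier"`.
#' @export
probabilisticClassifier <- function(name, type = c("tabular", "image"),
                                    fit, predict) {
  type <- match.arg(type)
  stopifnot(is.function(fit), is.function(predict))
  structure(list(name = name, type = type, fit = fit, predict = predict),
            class = "ProbabilisticClassifier")
}

#' CNN transfer-learning classifier
#'
#' Wraps [buildModel()]/[trainModel()]/[predictProb()] into the
#' [probabilisticClassifier()] contract. The training seed of each fit is the
#' seed supplied by the evaluation harness, keeping folds independently
#' reproducible.
#'
#' @param backbone A `"Backbone"` (default [tinyBackbone()]).
#' @param head A [headConfig()].
#' @param train A [trainConfig()]; its `seed` field is overridden per fit.
#' @return A `"ProbabilisticClassifier"` of type `"image"`.
#' @export
cnnClassifier <- function(backbone = tinyBackbone(), head = headConfig(),
                          train = trainConfig()) {
  force(backbone); force(head); force(train)
  probabilisticClassifier(
    name = paste0("cnn-", backbone$identifier),
    type = "image",
    fit = function(x, y, seed) {
      cfg <- train
      cfg$seed <- as.integer(seed)
      trainModel(buildModel(backbone, head), x, y, cfg)
    },
    predict = function(state, x) predictProb(state, x))
}

#' Random-forest baseline classifier
#'
#' @param ntree Number of trees.
#' @return A `"ProbabilisticClassifier"` of type `"tabular"`.
#' @export
randomForestClassifier <- function(ntree = 200L) {
  probabilisticClassifier(
    name = "random-forest", type = "tabular",
    fit = function(x, y, seed) {
      withSeed(seed, randomForest::randomForest(
        x = as.data.frame(x), y = factor(y, levels = c(0, 1)), ntree = ntree))
    },
    predict = function(state, x) {
      unname(stats::predict(state, as.data.frame(x), type = "prob")[, "1"])
    })
}

#' Logistic-regression baseline classifier
#'
#' Plain binomial GLM on the feature matrix; separable training sets produce
#' saturated probabilities, which is acceptable for ranking metrics.
#'
#' @return A `"ProbabilisticClassifier"` of type `"tabular"`.
#' @export
logisticClassifier <- function() {
  probabilisticClassifier(
    name = "logistic", type = "tabular",
    fit = function(x, y, seed) {
      df <- as.data.frame(x)
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(state, x) {
      p <- suppressWarnings(
        stats::predict(state, newdata = as.data.frame(x), type = "response"))
      unname(clamp(p, 0, 1))
    })
}
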