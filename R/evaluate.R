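#' Confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Named integer vector of class counts.
#' @export
confusionCounts <- function(TP, FP, TN, FN) {
  counts <- c(TP = as.integer(TP), FP = as.integer(FP),
              TN = as.integer(TN), FN = as.integer(FN))
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

#' Confusion counts from probabilities at a threshold
#'
#' Predicts positive when `prob >= threshold` (the tie at the threshold goes
#' to the positive class: in a screening setting sensitivity is favoured).
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold, default 0.5.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusionFromPredictions <- function(probs, labels, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  labels <- as.integer(labels)
  confusionCounts(sum(pred == 1 & labels == 1),
                  sum(pred == 1 & labels == 0),
                  sum(pred == 0 & labels == 0),
                  sum(pred == 0 & labels == 1))
}

zeroDenom <- function(what) {
  warning(what, " undefined (zero denominator); returning 0")
  0
}

#' Precision, recall and F1 from confusion counts
#'
#' `precisionScore = TP / (TP + FP)`, `recallScore = TP / (TP + FN)`,
#' `f1Score` is their harmonic mean. Zero-denominator cases return 0 with a
#' warning so report aggregation stays total.
#'
#' @param counts Named vector from [confusionCounts()].
#' @return A number in `[0, 1]`.
#' @export
precisionScore <- function(counts) {
  d <- counts[["TP"]] + counts[["FP"]]
  if (d == 0) return(zeroDenom("precision"))
  counts[["TP"]] / d
}

#' @rdname precisionScore
#' @export
recallScore <- function(counts) {
  d <- counts[["TP"]] + counts[["FN"]]
  if (d == 0) return(zeroDenom("recall"))
  counts[["TP"]] / d
}

#' @rdname precisionScore
#' @export
f1Score <- function(counts) {
  p <- suppressWarnings(precisionScore(counts))
  r <- suppressWarnings(recallScore(counts))
  if (p + r == 0) return(zeroDenom("F1"))
  2 * p * r / (p + r)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over every distinct score and reports the
#' (FPR, TPR) polyline and its trapezoidal area. The trapezoidal AUC equals
#' the Mann-Whitney pairwise statistic with ties counted one half.
#'
#' @param probs Scores (probabilities) for the positive class.
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `auc` and `points` (`data.frame` of `fpr`, `tpr`,
#'   starting at (0, 0) and ending at (1, 1)).
#' @export
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
rocAuc <- function(probs, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(probs, decreasing = TRUE)
  s <- probs[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))          # tie groups of equal scores
  tpCum <- cumsum(y == 1)
  fpCum <- cumsum(y == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpr = c(0, fpCum[last] / N), tpr = c(0, tpCum[last] / P))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(auc = auc, points = pts)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the binary
#' outcomes; lower is better calibrated. A constant 0.5 predictor scores 0.25.
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @return A number in `[0, 1]`.
#' @export
brierScore <- function(probs, labels) {
  stopifnot(all(probs >= 0 & probs <= 1))
  mean((probs - as.numeric(labels))^2)
}

#' Calibration curve
#'
#' Bins predictions into `nBins` equal-width probability bins and reports, per
#' non-empty bin, the mean predicted probability and the observed positive
#' frequency. A perfectly calibrated model lies on the diagonal.
#'
#' @param probs Probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @param nBins Number of equal-width bins, `>= 2`.
#' @return `data.frame` with columns `meanPred`, `obsFreq`, `count`.
#' @export
calibrationCurve <- function(probs, labels, nBins = 10L) {
  stopifnot(nBins >= 2)
  bin <- pmin(floor(probs * nBins) + 1L, nBins)
  labels <- as.numeric(labels)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(meanPred = mean(probs[idx]), obsFreq = mean(labels[idx]),
               count = sum(idx))
  }))
  rownames(out) <- NULL
  out
}

# Assemble an EvaluationReport from pooled held-out predictions.
buildReport <- function(probs, labels, threshold = 0.5, nBins = 10L,
                        folds = data.frame(), details = list()) {
  labels <- as.integer(labels)
  counts <- confusionFromPredictions(probs, labels, threshold)
  roc <- rocAuc(probs, labels)
  metrics <- list(precision = suppressWarnings(precisionScore(counts)),
                  recall = suppressWarnings(recallScore(counts)),
                  f1 = suppressWarnings(f1Score(counts)),
                  auc = roc$auc,
                  brier = brierScore(probs, labels))
  new("EvaluationReport", probs = as.numeric(probs), labels = labels,
      threshold = threshold, confusion = counts, metrics = metrics,
      rocPoints = roc$points,
      calibration = calibrationCurve(probs, labels, nBins),
      folds = folds, details = details)
}

# Fit a classifier on the training rows of one fold and return a closure that
# scores arbitrary rows. Image classifiers get per-fold normalization, bar
# encoding and fresh augmentation; held-out rows are encoded but never
# augmented. Test-time normalization clips silently: clipping is the designed
# behaviour for values outside the fold's fitted range.
fitOnFold <- function(dataset, trainIdx, classifier, seed, kAugment = 0L,
                      encoding = encodingConfig(),
                      augmentation = augmentationConfig(),
                      useDeclaredBounds = FALSE) {
  stopifnot(inherits(classifier, "ProbabilisticClassifier"))
  train <- subsetDataset(dataset, trainIdx)
  norm <- fitNormalizer(train, useDeclaredBounds = useDeclaredBounds)
  yTr <- classLabels(train)
  if (classifier$type == "tabular") {
    xTr <- applyNormalizer(featureValues(train), norm)
    state <- classifier$fit(xTr, yTr, seed)
    predictRows <- function(idx) {
      x <- suppressWarnings(
        applyNormalizer(featureValues(dataset)[idx, , drop = FALSE], norm))
      classifier$predict(state, x)
    }
    trainSize <- length(trainIdx)
  } else {
    vn <- applyNormalizer(featureValues(train), norm)
    imgs <- lapply(seq_len(nrow(vn)), function(i) encodeRecord(vn[i, ], encoding))
    aug <- augmentTrainingSet(imgs, yTr, kAugment, augmentation,
                              masterSeed = deriveSeed(seed, 1))
    state <- classifier$fit(aug$images, aug$labels, deriveSeed(seed, 2))
    predictRows <- function(idx) {
      x <- suppressWarnings(
        applyNormalizer(featureValues(dataset)[idx, , drop = FALSE], norm))
      testImgs <- lapply(seq_len(nrow(x)), function(i) encodeRecord(x[i, ], encoding))
      classifier$predict(state, testImgs)
    }
    trainSize <- length(aug$images)
  }
  list(predictRows = predictRows, trainSize = trainSize, normalizer = norm)
}

#' Leave-one-out cross-validation
#'
#' Runs exactly `n` folds; fold `i` fits the classifier on the other `n - 1`
#' records and scores the held-out record. For image classifiers the
#' normalization is refitted, the training records re-encoded and the training
#' images freshly augmented inside every fold with a fold-specific seed — the
#' held-out record is encoded but never augmented, so no augmented copy of it
#' can reach the training set.
#'
#' @param dataset A [TabularDataset-class] with both classes present.
#' @param classifier A [probabilisticClassifier()].
#' @param kAugment Augmentations per training image (image classifiers only);
#'   `k` augmentations turn `n - 1` training images into `(n - 1) * (k + 1)`.
#' @param encoding An [encodingConfig()] (image classifiers).
#' @param augmentation An [augmentationConfig()] (image classifiers).
#' @param seed Master seed; fold seeds are derived from it.
#' @param useDeclaredBounds Passed to [fitNormalizer()].
#' @param threshold Decision threshold for the confusion-based metrics.
#' @param calibrationBins Number of calibration bins.
#' @return An [EvaluationReport-class].
#' @export
runLoocv <- function(dataset, classifier, kAugment = 0L,
                     encoding = encodingConfig(),
                     augmentation = augmentationConfig(),
                     seed = 1L, useDeclaredBounds = FALSE,
                     threshold = 0.5, calibrationBins = 10L) {
  n <- nSamples(dataset)
  if (n < 2) stop("LOOCV needs at least 2 records")
  if (length(unique(classLabels(dataset))) < 2) {
    stop("dataset must contain both classes")
  }
  probs <- numeric(n)
  folds <- data.frame(fold = seq_len(n), heldOut = seq_len(n),
                      seed = NA_integer_, trainSize = NA_integer_)
  for (i in seq_len(n)) {
    foldSeed <- deriveSeed(seed, i)
    folds$seed[i] <- foldSeed
    fit <- tryCatch(
      fitOnFold(dataset, setdiff(seq_len(n), i), classifier, foldSeed,
                kAugment = kAugment, encoding = encoding,
                augmentation = augmentation,
                useDeclaredBounds = useDeclaredBounds),
      error = function(e) stop("fold ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    probs[i] <- fit$predictRows(i)
    folds$trainSize[i] <- fit$trainSize
    t2iLog("loocv", sprintf("fold %d/%d trained on %d images/rows",
                            i, n, fit$trainSize), "DEBUG")
  }
  buildReport(probs, classLabels(dataset), threshold, calibrationBins,
              folds = folds,
              details = list(classifier = classifier$name,
                             kAugment = as.integer(kAugment),
                             seed = as.integer(seed)))
}

#' @rdname heldOutProbs
setMethod("heldOutProbs", "EvaluationReport", function(x) x@probs)
#' @rdname reportMetrics
setMethod("reportMetrics", "EvaluationReport", function(x) x@metrics)

setMethod("show", "EvaluationReport", function(object) {
  m <- object@metrics
  cat("EvaluationReport:", length(object@probs), "held-out predictions\n")
  cat(sprintf("  threshold %.2f | TP %d FP %d TN %d FN %d\n", object@threshold,
              object@confusion[["TP"]], object@confusion[["FP"]],
              object@confusion[["TN"]], object@confusion[["FN"]]))
  cat(sprintf("  precision %.3f recall %.3f F1 %.3f AUC %.3f Brier %.4f\n",
              m$precision, m$recall, m$f1, m$auc, m$brier))
})
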