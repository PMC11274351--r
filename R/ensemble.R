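#' Hard (majority) vote
#'
#' Returns the label receiving the most votes. Ties are broken toward the
#' positive class: in a screening context sensitivity is favoured (the
#' five-member panel used in practice is odd and never ties).
#'
#' @param votes Vector of 0/1 votes, non-empty.
#' @return A single 0/1 label.
#' @export
#' @examples
#' hardVote(c(1, 1, 0))  # 1
#' hardVote(c(1, 0))     # 1 (tie toward positive)
hardVote <- function(votes) {
  stopifnot(length(votes) > 0, all(votes %in% c(0, 1)))
  as.integer(mean(votes) >= 0.5)
}

#' Soft (probability-averaging) vote
#'
#' Averages the members' positive-class probabilities and labels positive when
#' the mean reaches the threshold (`>=` convention, consistent with
#' [hardVote()]'s tie-break).
#'
#' @param probs Vector of probabilities in `[0, 1]`, non-empty.
#' @param threshold Decision threshold, default 0.5.
#' @return List with `prob` (the mean) and `label`.
#' @export
#' @examples
#' softVote(c(0.6, 0.8))  # prob 0.7, label 1
softVote <- function(probs, threshold = 0.5) {
  stopifnot(length(probs) > 0)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  m <- mean(probs)
  list(prob = m, label = as.integer(m >= threshold))
}

#' Declare a level-1 ensemble member
#'
#' Pairs a classifier factory with its own augmentation level, so that
#' image-based members at different augmentation levels (e.g. no augmentation
#' vs nine augmentations per image) can sit in the same ensemble alongside
#' tabular members.
#'
#' @param classifier A [probabilisticClassifier()].
#' @param kAugment Augmentations per training image (image members only).
#' @param name Display name; defaults to the classifier's.
#' @return A list of class `"EnsembleMember"`.
#' @export
ensembleMember <- function(classifier, kAugment = 0L, name = classifier$name) {
  stopifnot(inherits(classifier, "ProbabilisticClassifier"), kAugment >= 0)
  structure(list(classifier = classifier, kAugment = as.integer(kAugment),
                 name = name),
            class = "EnsembleMember")
}

#' Random-forest meta-classifier factory
#'
#' The meta-classifier trained on the level-1 members' predicted
#' probabilities in the stacking ensemble.
#'
#' @param ntree Number of trees.
#' @return A meta-factory: list with `fit(X, y, seed)` and
#'   `predict(state, X)`.
#' @export
rfMetaFactory <- function(ntree = 200L) {
  list(
    fit = function(X, y, seed) {
      withSeed(seed, randomForest::randomForest(
        x = as.data.frame(X), y = factor(y, levels = c(0, 1)), ntree = ntree))
    },
    predict = function(state, X) {
      unname(stats::predict(state, as.data.frame(X), type = "prob")[, "1"])
    })
}

#' Pass-through meta-classifier
#'
#' Returns the first member's probability unchanged. With a single member this
#' makes the stack degenerate to that member's own cross-validated
#' predictions, which is useful as a protocol check.
#'
#' @return A meta-factory (see [rfMetaFactory()]).
#' @export
passthroughMeta <- function() {
  list(fit = function(X, y, seed) NULL,
       predict = function(state, X) X[, 1])
}

#' Mean meta-classifier
#'
#' A deterministic meta that ignores the training data and averages the member
#' probabilities (a fitted soft vote).
#'
#' @return A meta-factory (see [rfMetaFactory()]).
#' @export
meanMeta <- function() {
  list(fit = function(X, y, seed) NULL,
       predict = function(state, X) rowMeans(X))
}

# Stratified inner-fold assignment for out-of-fold meta-features.
innerAssignment <- function(labels, k, seed) {
  withSeed(seed, {
    assign <- integer(length(labels))
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      assign[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
    assign
  })
}

#' Stacking ensemble under leave-one-out cross-validation
#'
#' For each of the `n` outer folds the level-1 members are fitted on the
#' `n - 1` training records (image members with their own fresh per-fold
#' augmentation), the meta-classifier is trained on member probabilities for
#' the training fold, and the stacked model then scores the held-out record.
#'
#' By default the meta-classifier is trained on *out-of-fold* member
#' probabilities from an inner `innerFolds`-fold split of the training fold,
#' so the meta never sees a probability produced by a model that was trained
#' on the same record — in-sample level-1 predictions would leak optimism into
#' the meta-features. `metaInsample = TRUE` reproduces the simpler protocol in
#' which members fitted on the whole training fold score it in-sample.
#'
#' @param dataset A [TabularDataset-class].
#' @param members List of [ensembleMember()] (a bare classifier is wrapped
#'   automatically).
#' @param meta A meta-factory, default [rfMetaFactory()].
#' @param innerFolds Inner folds for out-of-fold meta-features.
#' @param metaInsample Train the meta on in-sample member predictions instead.
#' @param encoding,augmentation Image pipeline settings shared by image
#'   members.
#' @param seed Master seed.
#' @param useDeclaredBounds Passed to [fitNormalizer()].
#' @param threshold,calibrationBins Report settings.
#' @return An [EvaluationReport-class]; `@details$audit` records, per fold,
#'   every index set used to fit any model, for leakage auditing.
#' @export
stackLoocv <- function(dataset, members, meta = rfMetaFactory(),
                       innerFolds = 5L, metaInsample = FALSE,
                       encoding = encodingConfig(),
                       augmentation = augmentationConfig(),
                       seed = 1L, useDeclaredBounds = FALSE,
                       threshold = 0.5, calibrationBins = 10L) {
  members <- lapply(members, function(m) {
    if (inherits(m, "EnsembleMember")) m else ensembleMember(m)
  })
  n <- nSamples(dataset)
  y <- classLabels(dataset)
  nm <- length(members)
  stopifnot(nm >= 1)
  probs <- numeric(n)
  audit <- vector("list", n)
  fitMember <- function(j, trainIdx, sd) {
    fitOnFold(dataset, trainIdx, members[[j]]$classifier, sd,
              kAugment = members[[j]]$kAugment, encoding = encoding,
              augmentation = augmentation,
              useDeclaredBounds = useDeclaredBounds)
  }
  for (i in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), i)
    foldAudit <- list(heldOut = i, outerTrain = trainIdx, fits = list())
    res <- tryCatch({
      # members fitted on the full training fold score the held-out record
      outerFits <- lapply(seq_len(nm), function(j) {
        fitMember(j, trainIdx, deriveSeed(seed, i, j))
      })
      for (j in seq_len(nm)) {
        foldAudit$fits[[length(foldAudit$fits) + 1L]] <-
          list(member = members[[j]]$name, rows = trainIdx, role = "outer")
      }
      if (metaInsample) {
        Z <- vapply(outerFits, function(f) f$predictRows(trainIdx),
                    numeric(length(trainIdx)))
      } else {
        k <- min(innerFolds, min(table(y[trainIdx])))
        if (k < 2) {
          stop("too few records per class for out-of-fold meta-features; ",
               "use metaInsample = TRUE")
        }
        assign <- innerAssignment(y[trainIdx], k, deriveSeed(seed, i, 0))
        Z <- matrix(NA_real_, length(trainIdx), nm)
        for (f in seq_len(k)) {
          innerTest <- trainIdx[assign == f]
          innerTrain <- setdiff(trainIdx, innerTest)
          for (j in seq_len(nm)) {
            fitJ <- fitMember(j, innerTrain, deriveSeed(seed, i, j, f))
            Z[assign == f, j] <- fitJ$predictRows(innerTest)
            foldAudit$fits[[length(foldAudit$fits) + 1L]] <-
              list(member = members[[j]]$name, rows = innerTrain,
                   role = paste0("inner", f))
          }
        }
      }
      metaState <- meta$fit(Z, y[trainIdx], deriveSeed(seed, i, 99))
      foldAudit$metaTrainRows <- trainIdx
      zHeld <- matrix(vapply(outerFits, function(f) f$predictRows(i),
                             numeric(1)), nrow = 1)
      clamp(meta$predict(metaState, zHeld), 0, 1)
    }, error = function(e) {
      stop("fold ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    probs[i] <- res
    audit[[i]] <- foldAudit
    t2iLog("stack", sprintf("fold %d/%d done", i, n), "DEBUG")
  }
  folds <- data.frame(fold = seq_len(n), heldOut = seq_len(n),
                      seed = vapply(seq_len(n), function(i) deriveSeed(seed, i),
                                    integer(1)),
                      trainSize = n - 1L)
  buildReport(probs, y, threshold, calibrationBins, folds = folds,
              details = list(members = vapply(members, `[[`, "", "name"),
                             metaFeatureDim = nm,
                             metaInsample = metaInsample,
                             seed = as.integer(seed),
                             audit = audit))
}
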