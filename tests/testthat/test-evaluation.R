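test_that("precision, recall and F1 follow their formulas and conventions", {
  expect_equal(precisionScore(confusionCounts(3, 1, 0, 0)), 0.75)
  expect_equal(recallScore(confusionCounts(3, 0, 0, 1)), 0.75)
  # precision = recall = p implies F1 = p
  c1 <- confusionCounts(3, 1, 5, 1)
  expect_equal(f1Score(c1), precisionScore(c1))
  expect_warning(p0 <- precisionScore(confusionCounts(0, 0, 5, 2)),
                 "zero denominator")
  expect_equal(p0, 0)
})

test_that("rocAuc equals the brute-force pairwise statistic on random cases", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(6:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      probs <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
      r <- rocAuc(probs, labels)
      expect_equal(r$auc, pairwiseAuc(probs, labels), tolerance = 1e-12)
      expect_false(is.unsorted(r$points$fpr))
      expect_false(is.unsorted(r$points$tpr))
    }
  })
})

test_that("rocAuc endpoints: perfect separation 1, label-free scores near 0.5", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  withr::with_seed(3, {
    probs <- runif(4000)
    labels <- rbinom(4000, 1, 0.5)
  })
  expect_lt(abs(rocAuc(probs, labels)$auc - 0.5), 0.03)
  expect_error(rocAuc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(4, {
    probs <- runif(50)
    labels <- rbinom(50, 1, 0.4)
  })
  a <- rocAuc(probs, labels)$auc
  expect_equal(rocAuc(plogis(5 * probs - 2), labels)$auc, a, tolerance = 1e-12)
  expect_equal(rocAuc(probs^3, labels)$auc, a, tolerance = 1e-12)
})

test_that("rocAuc agrees with an independent ROC implementation", {
  withr::with_seed(5, {
    probs <- runif(60)
    labels <- rbinom(60, 1, 0.5)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, probs, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rocAuc(probs, labels)$auc, ref, tolerance = 1e-12)
})

test_that("brierScore matches direct recomputation and closed forms", {
  expect_equal(brierScore(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brierScore(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  withr::with_seed(6, {
    p <- runif(40); y <- rbinom(40, 1, 0.5)
  })
  expect_equal(brierScore(p, y), sum((p - y)^2) / 40, tolerance = 1e-12)
})

test_that("calibration bins: direct cases and a calibrated simulation", {
  b <- calibrationCurve(c(0.1, 0.9), c(0, 1), nBins = 2)
  expect_equal(b$meanPred, c(0.1, 0.9))
  expect_equal(b$obsFreq, c(0, 1))
  one <- calibrationCurve(rep(1, 5), rep(1, 5), nBins = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$meanPred, 1)
  withr::with_seed(7, {
    p <- runif(20000)
    y <- rbinom(20000, 1, p)
  })
  cal <- calibrationCurve(p, y, nBins = 10)
  expect_equal(nrow(cal), 10)
  expect_true(all(abs(cal$meanPred - cal$obsFreq) < 0.05))
})

test_that("LOOCV holds each record out exactly once and trains on n-1", {
  ds <- oracleDataset(10)
  store <- newStore()
  rep <- runLoocv(ds, recordingImageClassifier(store), kAugment = 0,
                  encoding = quickEnc(), seed = 2)
  expect_equal(rep@folds$heldOut, 1:10)
  expect_equal(rep@folds$trainSize, rep(9L, 10))
  expect_length(store$trainSets, 10)
  # a perfect-oracle tabular classifier yields perfect pooled metrics
  perfect <- runLoocv(ds, firstFeatureClassifier(), seed = 3)
  m <- reportMetrics(perfect)
  expect_equal(unlist(m[c("precision", "recall", "f1", "auc")]),
               c(precision = 1, recall = 1, f1 = 1, auc = 1))
})

test_that("a constant-probability classifier scores AUC 0.5 and Brier 0.25", {
  ds <- oracleDataset(10)
  rep <- runLoocv(ds, constantClassifier(0.5), seed = 4)
  expect_equal(reportMetrics(rep)$auc, 0.5)
  expect_equal(reportMetrics(rep)$brier, 0.25)
})

test_that("fresh per-fold augmentation never touches the held-out image", {
  # both features vary per record and no record is extreme in both features,
  # so per-fold refitting + clipping can never make two records encode to the
  # same raster and the identity audit below is unambiguous
  ds <- tabularDataset(toySchema(),
                       cbind(c(0, 1, 2, 3, 7, 8, 9, 10),
                             c(5, 2, 8, 4, 6, 9, 3, 7)),
                       rep(c(0L, 1L), each = 4))
  store <- newStore()
  rep <- runLoocv(ds, recordingImageClassifier(store), kAugment = 2,
                  encoding = quickEnc(), augmentation = pipeAug(), seed = 6)
  expect_equal(rep@folds$trainSize, rep(7L * 3L, 8))
  # reproduce each fold's held-out encoding and check it is absent from the
  # training set the classifier saw (leakage audit)
  for (i in seq_len(8)) {
    train <- subsetDataset(ds, setdiff(1:8, i))
    norm <- fitNormalizer(train)
    held <- pixels(encodeRecord(
      suppressWarnings(applyNormalizer(featureValues(ds)[i, ], norm)),
      quickEnc()))
    seen <- store$trainSets[[i]]
    expect_false(any(vapply(seen, function(im) identical(im, held),
                            logical(1))))
  }
})

test_that("evaluation reports serialize to JSON and back unchanged", {
  ds <- oracleDataset(10)
  rep <- runLoocv(ds, firstFeatureClassifier(), seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  writeEvaluationReport(rep, path)
  rt <- readEvaluationReport(path)
  expect_equal(rt@probs, rep@probs)
  expect_equal(rt@metrics, rep@metrics)
  expect_equal(rt@confusion, rep@confusion)
  expect_equal(rt@rocPoints, rep@rocPoints)
})
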