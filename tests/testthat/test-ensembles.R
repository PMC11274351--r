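test_that("hardVote matches exhaustive majority for every pattern up to k = 5", {
  for (k in 1:5) {
    patterns <- expand.grid(rep(list(c(0, 1)), k))
    for (r in seq_len(nrow(patterns))) {
      votes <- as.numeric(patterns[r, ])
      expected <- if (sum(votes == 1) > sum(votes == 0)) 1L else
        if (sum(votes == 1) < sum(votes == 0)) 0L else 1L  # tie -> positive
      expect_identical(hardVote(votes), expected)
    }
  }
  expect_identical(hardVote(c(1, 1, 0)), 1L)
  expect_identical(hardVote(c(0, 0, 0, 1, 1)), 0L)
  expect_identical(hardVote(c(1, 0)), 1L)
})

test_that("softVote averages, applies the >= threshold and validates input", {
  expect_equal(softVote(c(0.6, 0.8)), list(prob = 0.7, label = 1L))
  expect_equal(softVote(c(0.5, 0.5, 0.5))$label, 1L)
  expect_error(softVote(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(31, {
    for (i in 1:5) {
      p <- runif(5)
      expect_equal(softVote(p)$prob, sum(p) / 5, tolerance = 1e-12)
      expect_equal(softVote(sample(p))$prob, softVote(p)$prob)  # permutation
    }
  })
})

test_that("a single member with a pass-through meta degenerates to its LOOCV", {
  ds <- oracleDataset(8)
  member <- firstFeatureClassifier()
  stacked <- stackLoocv(ds, list(member), meta = passthroughMeta(),
                        metaInsample = TRUE, seed = 5)
  direct <- runLoocv(ds, member, seed = 5)
  expect_equal(heldOutProbs(stacked), heldOutProbs(direct))
})

test_that("stacking on a six-record toy matches a hand-executed protocol", {
  sch <- toySchema(1)
  ds <- tabularDataset(sch, matrix(c(1, 2, 3, 4, 5, 6)), c(0L, 0L, 0L, 1L, 1L, 1L))
  # member A: the normalized feature itself; member B: a fixed threshold rule
  a <- firstFeatureClassifier()
  b <- probabilisticClassifier("rule", "tabular",
                               fit = function(x, y, seed) NULL,
                               predict = function(state, x) {
                                 ifelse(x[, 1] >= 0.5, 0.9, 0.1)
                               })
  got <- stackLoocv(ds, list(a, b), meta = meanMeta(), metaInsample = TRUE,
                    seed = 1)
  # hand execution: fold i fits min-max on the other 5 raw values, scores the
  # held-out value with both rules, and the mean meta averages them
  expected <- vapply(1:6, function(i) {
    train <- (1:6)[-i]
    lo <- min(train); hi <- max(train)
    v <- min(max((i - lo) / (hi - lo), 0), 1)
    mean(c(v, ifelse(v >= 0.5, 0.9, 0.1)))
  }, numeric(1))
  expect_equal(heldOutProbs(got), expected, tolerance = 1e-12)
  expect_equal(got@details$metaFeatureDim, 2)
})

test_that("no model that scores record i is ever fitted on record i", {
  ds <- oracleDataset(8)
  members <- list(firstFeatureClassifier(), constantClassifier(0.4))
  rep <- stackLoocv(ds, members, meta = rfMetaFactory(ntree = 30),
                    innerFolds = 2, seed = 9)
  audit <- rep@details$audit
  expect_length(audit, 8)
  for (fold in audit) {
    expect_false(fold$heldOut %in% fold$outerTrain)
    expect_false(fold$heldOut %in% fold$metaTrainRows)
    for (fit in fold$fits) {
      expect_false(fold$heldOut %in% fit$rows)
    }
    # out-of-fold meta-features: inner fits exist besides the outer ones
    roles <- vapply(fold$fits, `[[`, "", "role")
    expect_true(any(grepl("inner", roles)))
  }
})

test_that("stacking stays within 0.05 AUC of its best member on synthetic data", {
  # members of unequal quality (two real classifiers plus pure noise) on a
  # cohort where the real members are strong, mirroring the regime in which
  # stacking is used in practice
  hits <- 0
  for (seed in 1:5) {
    ds <- generateCohort(separabilityProfile(2, 25, 25), seed = 400 + seed)
    members <- list(
      ensembleMember(logisticClassifier(), name = "logistic"),
      ensembleMember(randomForestClassifier(ntree = 100), name = "rf"),
      ensembleMember(constantClassifier(0.5), name = "noise"))
    stacked <- stackLoocv(ds, members, meta = rfMetaFactory(ntree = 100),
                          innerFolds = 3, seed = seed)
    best <- max(vapply(list(logisticClassifier(),
                            randomForestClassifier(ntree = 100)),
                       function(cl) {
                         reportMetrics(runLoocv(ds, cl, seed = seed))$auc
                       }, numeric(1)))
    hits <- hits + (reportMetrics(stacked)$auc >= best - 0.05)
  }
  expect_gte(hits, 4)
})
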