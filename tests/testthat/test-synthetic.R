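test_that("the default profile reproduces the cohort's size and class split", {
  ds <- generateCohort(defaultProstateProfile(), seed = 1)
  expect_equal(nSamples(ds), 84)
  expect_equal(as.numeric(table(classLabels(ds))), c(45, 39))
  expect_equal(featureNames(ds),
               c("PSA", "Age", "IEBladder", "UrinateAgain", "Intermittency",
                 "Urgency", "Nocturia", "Straining", "WeakUrine"))
  # ordinal columns are integer category codes inside 0..5
  v <- featureValues(ds)
  for (nm in featureNames(ds)[-(1:2)]) {
    expect_true(all(v[, nm] %in% 0:5))
  }
  expect_identical(featureValues(generateCohort(defaultProstateProfile(), seed = 1)), v)
  expect_false(identical(
    featureValues(generateCohort(defaultProstateProfile(), seed = 2)), v))
})

test_that("two calls to the profile constructors give identical configs", {
  expect_identical(defaultProstateProfile(), defaultProstateProfile())
  expect_identical(separabilityProfile(2), separabilityProfile(2))
})

test_that("invalid generator configurations are rejected", {
  bad <- defaultProstateProfile()
  expect_error(generatorConfig(bad$schema, 45, 39, bad$margins,
                               diag(-1, 9)), "diagonal|positive")
  R <- bad$correlation
  R[1, 2] <- 0.99; R[2, 1] <- 0.99; R[1, 3] <- -0.99; R[3, 1] <- -0.99
  R[2, 3] <- 0.99; R[3, 2] <- 0.99
  expect_error(generatorConfig(bad$schema, 45, 39, bad$margins, R),
               "positive-definite")
})

test_that("class-conditional margins and correlations match the profile", {
  big <- defaultProstateProfile()
  big$nNegative <- 5000L
  big$nPositive <- 5000L
  ds <- generateCohort(big, seed = 10)
  v <- featureValues(ds)
  y <- classLabels(ds)
  # positives: higher, narrower PSA
  expect_gt(mean(v[y == 1, "PSA"]), mean(v[y == 0, "PSA"]))
  expect_lt(sd(log(v[y == 1, "PSA"] + 1e-9)), sd(log(v[y == 0, "PSA"] + 1e-9)))
  # elevated symptom categories for the strong features
  expect_gt(mean(v[y == 1, "IEBladder"]), mean(v[y == 0, "IEBladder"]))
  expect_gt(mean(v[y == 1, "Urgency"]), mean(v[y == 0, "Urgency"]))
  # rank correlations recover the configured ordering within each class
  sp <- function(a, b) cor(v[y == 0, a], v[y == 0, b], method = "spearman")
  expect_lt(abs(sp("Urgency", "IEBladder") - 0.55), 0.1)
  expect_true(sp("Urgency", "IEBladder") > sp("PSA", "Urgency"))
  expect_true(sp("PSA", "Urgency") > sp("IEBladder", "UrinateAgain"))
  expect_gt(sp("IEBladder", "UrinateAgain"), 0.1)
})

test_that("a null cohort gives chance-level LOOCV and large effects separate", {
  nullDs <- generateCohort(separabilityProfile(0, 20, 20), seed = 5)
  auc <- reportMetrics(runLoocv(nullDs, logisticClassifier(), seed = 5))$auc
  expect_lt(abs(auc - 0.5), 0.28)  # within ~3 SE of chance at this n
  hits <- 0
  for (seed in 1:5) {
    sep <- generateCohort(separabilityProfile(3), seed = 500 + seed)
    a <- reportMetrics(runLoocv(sep, logisticClassifier(), seed = seed))$auc
    hits <- hits + (a >= 0.95)
  }
  expect_gte(hits, 4)
})

test_that("LOOCV AUC grows with the separation scale (rank over 3 levels)", {
  means <- vapply(c(0.25, 1, 3), function(s) {
    mean(vapply(1:5, function(seed) {
      ds <- generateCohort(separabilityProfile(s, 25, 25), seed = 600 + seed)
      reportMetrics(runLoocv(ds, logisticClassifier(), seed = seed))$auc
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(means))
})

test_that("generated datasets always validate against their schema", {
  for (seed in 1:3) {
    expect_s4_class(generateCohort(separabilityProfile(seed / 2, 10, 10),
                                   seed = seed), "TabularDataset")
  }
})
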