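test_that("elastic distortion: zero strength is the identity, fixed seed fixed output", {
  img <- pixels(encodeRecord(runif(9), quickEnc()))
  expect_identical(elasticDistort(img, 0, 3, seed = 5), img)
  a <- elasticDistort(img, 60, 3, seed = 5)
  b <- elasticDistort(img, 60, 3, seed = 5)
  expect_identical(a, b)
  expect_error(elasticDistort(img, 10, 0), "sigma")
})

test_that("a strong distortion moves at least one pixel of a half-filled image", {
  img <- pixels(encodeRecord(rep(0.5, 9), encodingConfig(640, 480)))
  out <- elasticDistort(img, 60, 3, seed = 1)
  expect_gt(sum(out != img), 0)
  expect_equal(dim(out), dim(img))
})

test_that("morphology: no-op probabilities and 1x1 elements leave the image alone", {
  img <- pixels(encodeRecord(runif(9), quickEnc()))
  expect_identical(randomMorphology(img, 0, 0, seed = 3), img)
  expect_identical(barDilate(img, 1, 1), img)
  expect_identical(barErode(img, 1, 1), img)
})

test_that("forced dilation strictly grows a half-width bar", {
  img <- pixels(encodeRecord(rep(0.5, 9), quickEnc()))
  out <- randomMorphology(img, 1, 0, seed = 9)
  expect_gte(nonBackgroundCount(out), nonBackgroundCount(img))
  grown <- barDilate(img, 1, 3)
  expect_gt(nonBackgroundCount(grown), nonBackgroundCount(img))
})

test_that("dilation never shrinks and erosion never grows the bars (100 draws)", {
  withr::with_seed(17, {
    for (i in 1:100) {
      v <- runif(9)
      img <- pixels(encodeRecord(v, quickEnc()))
      n0 <- nonBackgroundCount(img)
      seH <- sample(1:2, 1)
      seW <- sample(1:5, 1)
      expect_gte(nonBackgroundCount(barDilate(img, seH, seW)), n0)
      expect_lte(nonBackgroundCount(barErode(img, seH, seW)), n0)
    }
  })
})

test_that("augmentImage: degenerate config is the identity, seeds reproduce", {
  img <- pixels(encodeRecord(runif(9), quickEnc()))
  idCfg <- augmentationConfig(alphaRange = c(0, 0), sigmaRange = c(1, 1),
                              pDilateRange = c(0, 0), pErodeRange = c(0, 0))
  expect_identical(augmentImage(img, idCfg, seed = 2), img)
  cfg <- pipeAug()
  expect_identical(augmentImage(img, cfg, seed = 4),
                   augmentImage(img, cfg, seed = 4))
  expect_false(identical(augmentImage(img, cfg, seed = 4),
                         augmentImage(img, cfg, seed = 5)))
})

test_that("nearest-neighbour elastic distortion preserves the colour inventory", {
  img <- encodeRecord(seq(0.2, 0.7, length.out = 9), pipeEnc())
  key <- function(px) {
    m <- matrix(px, ncol = 3)
    unique(paste(m[, 1], m[, 2], m[, 3]))
  }
  out <- elasticDistort(img, 15, 1, seed = 6, interpolation = "nearest")
  expect_true(all(key(out) %in% key(pixels(img))))
  # the full nearest-mode augmentation only ever adds channel-wise
  # combinations of palette colours and background, never interpolated shades
  full <- augmentImage(img, pipeAug("nearest"), seed = 6)
  channelValues <- sort(unique(as.vector(pixels(img))))
  expect_true(all(unique(as.vector(full)) %in% channelValues))
})

test_that("augmentTrainingSet: n*(k+1) images, labels replicated, reproducible", {
  imgs <- lapply(1:3, function(i) encodeRecord(runif(9), quickEnc()))
  labels <- c(0L, 1L, 1L)
  cfg <- pipeAug()
  out <- augmentTrainingSet(imgs, labels, k = 2, cfg, masterSeed = 13)
  expect_length(out$images, 9)
  expect_equal(out$labels, c(labels, rep(labels, each = 2)))
  expect_equal(mean(out$labels), mean(labels))  # class balance preserved
  out2 <- augmentTrainingSet(imgs, labels, k = 2, cfg, masterSeed = 13)
  expect_identical(out$images, out2$images)
  expect_error(augmentTrainingSet(imgs, labels, k = -1, cfg, 1), "k")
  expect_length(augmentTrainingSet(imgs, labels, 0, cfg, 1)$images, 3)
})
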