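# Shared fixtures: small geometries and cheap classifiers so tests stay fast.

# Coarse raster for structural checks (slot width 8 px with 9 features).
quickEnc <- function() encodingConfig(72, 48)

# Pipeline-scale raster: one quarter of the full 640 x 480, with elastic
# parameters scaled by the same factor so distortions are geometrically
# equivalent.
pipeEnc <- function() encodingConfig(160, 120)
pipeAug <- function(interpolation = "bilinear") {
  augmentationConfig(alphaRange = c(10, 15), sigmaRange = c(0.75, 1.25),
                     interpolation = interpolation)
}

# Two-feature toy schema on [0, 10].
toySchema <- function(m = 2) {
  do.call(featureSchema, lapply(seq_len(m), function(i) {
    featureSpec(paste0("x", i), "continuous", 0, 10)
  }))
}

# Dataset whose first feature is a perfect predictor (0 or 10 by class); the
# second feature is a deterministic spread so every record encodes uniquely.
oracleDataset <- function(n = 10, seed = 1) {
  stopifnot(n %% 2 == 0)
  labels <- rep(c(0L, 1L), each = n / 2)
  v <- cbind(ifelse(labels == 1, 10, 0), seq(0.5, 9.5, length.out = n))
  tabularDataset(toySchema(), v, labels)
}

# Tabular classifier that returns the (normalized) first feature as the
# probability; deterministic, no fitting.
firstFeatureClassifier <- function() {
  probabilisticClassifier("first-feature", "tabular",
                          fit = function(x, y, seed) NULL,
                          predict = function(state, x) unname(x[, 1]))
}

# Tabular classifier with a constant probability.
constantClassifier <- function(p = 0.5) {
  probabilisticClassifier("constant", "tabular",
                          fit = function(x, y, seed) NULL,
                          predict = function(state, x) rep(p, nrow(x)))
}

# Image classifier that records every training set it sees (for fold and
# leakage audits) and predicts a constant.
recordingImageClassifier <- function(store, p = 0.5) {
  probabilisticClassifier("recorder", "image",
    fit = function(x, y, seed) {
      store$trainSets[[length(store$trainSets) + 1L]] <- x
      store$trainSizes <- c(store$trainSizes, length(x))
      NULL
    },
    predict = function(state, x) rep(p, length(x)))
}

newStore <- function() {
  e <- new.env()
  e$trainSets <- list()
  e$trainSizes <- integer(0)
  e
}

# Brute-force pairwise AUC oracle (Mann-Whitney with ties counted 1/2).
pairwiseAuc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
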