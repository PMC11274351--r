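#' @import methods
NULL

#' FeatureSchema: ordered feature declarations
#'
#' An ordered set of feature declarations — one row per feature with its name,
#' kind (`"continuous"` or `"ordinal"`), domain bounds and display colour
#' index. The schema is the single source of truth for the number of features
#' `m` and for the encoding order of the bars in the image representation.
#'
#' @slot features A `data.frame` with columns `name`, `kind`, `domainMin`,
#'   `domainMax`, `colorIndex`, one row per feature, in encoding order.
#' @seealso [featureSchema()], [prostateSchema()]
#' @export
setClass("FeatureSchema", representation(features = "data.frame"))

setValidity("FeatureSchema", function(object) {
  f <- object@features
  need <- c("name", "kind", "domainMin", "domainMax", "colorIndex")
  if (!all(need %in% names(f))) {
    return(paste("features must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(f) < 1) return("a schema needs at least one feature")
  if (anyDuplicated(f$name)) return("feature names must be unique")
  if (anyDuplicated(f$colorIndex)) return("colour indices must be unique")
  if (!all(f$kind %in% c("continuous", "ordinal"))) {
    return("kind must be 'continuous' or 'ordinal'")
  }
  if (!all(f$domainMin < f$domainMax)) {
    return("domainMin must be < domainMax for every feature")
  }
  ord <- f$kind == "ordinal"
  if (any(ord) && !all(f$domainMin[ord] == round(f$domainMin[ord]) &
                       f$domainMax[ord] == round(f$domainMax[ord]))) {
    return("ordinal domains must have integer bounds")
  }
  if (any(f$colorIndex < 0)) return("colorIndex must be >= 0")
  TRUE
})

#' TabularDataset: records, features and binary labels
#'
#' Holds `n` records of `m` features together with a binary diagnosis label
#' (1 = positive/carcinoma) and the [FeatureSchema-class] the columns conform
#' to. Ordinal columns must hold integers inside their declared domain.
#'
#' @slot schema A [FeatureSchema-class].
#' @slot values An `n x m` numeric matrix, columns in schema order.
#' @slot labels An integer vector of 0/1 labels of length `n`.
#' @seealso [tabularDataset()], [generateCohort()], [readTabularDataset()]
#' @export
setClass("TabularDataset",
         representation(schema = "FeatureSchema",
                        values = "matrix",
                        labels = "integer"))

setValidity("TabularDataset", function(object) {
  v <- object@values
  f <- object@schema@features
  if (ncol(v) != nrow(f)) return("value columns must match schema features")
  if (!identical(colnames(v), f$name)) {
    return("value column names must equal schema feature names, in order")
  }
  if (nrow(v) != length(object@labels)) return("one label per record required")
  if (nrow(v) < 2) return("a dataset needs at least 2 records")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (any(!is.finite(v))) return("values must be finite (missing data are not supported)")
  ord <- which(f$kind == "ordinal")
  for (j in ord) {
    x <- v[, j]
    if (any(x != round(x)) || any(x < f$domainMin[j]) || any(x > f$domainMax[j])) {
      return(sprintf("ordinal feature '%s' must hold integers in [%d, %d]",
                     f$name[j], f$domainMin[j], f$domainMax[j]))
    }
  }
  TRUE
})

#' Normalizer: fitted min-max scaling parameters
#'
#' Per-feature fitted minima and maxima for min-max scaling to `[0, 1]`.
#' Constant features (fitted min equal to fitted max) are flagged and always
#' normalize to 0.
#'
#' @slot fittedMin,fittedMax Numeric vectors, one entry per feature.
#' @slot featureNames Character vector naming the features, in schema order.
#' @seealso [fitNormalizer()], [applyNormalizer()]
#' @export
setClass("Normalizer",
         representation(fittedMin = "numeric",
                        fittedMax = "numeric",
                        featureNames = "character"))

setValidity("Normalizer", function(object) {
  m <- length(object@featureNames)
  if (length(object@fittedMin) != m || length(object@fittedMax) != m) {
    return("fittedMin/fittedMax must have one entry per feature")
  }
  if (any(object@fittedMin > object@fittedMax)) {
    return("fittedMin must be <= fittedMax")
  }
  TRUE
})

#' EncodedImage: bar-chart raster of one record
#'
#' The image representation of a single record: an `h x w x 3` raster on the
#' 0..255 scale in which feature `i` occupies a fixed horizontal slot and is
#' painted as a left-anchored, full-height bar of width proportional to its
#' normalized value.
#'
#' @slot pixels Numeric `h x w x 3` array with values in `[0, 255]`.
#' @slot slotBounds Integer vector of `m + 1` x-coordinates: slot `i` spans
#'   pixel columns `slotBounds[i] + 1` to `slotBounds[i + 1]`.
#' @slot palette Integer `m x 3` matrix of the per-feature RGB colours.
#' @slot sourceVector The normalized record the image was encoded from
#'   (may be length 0 when provenance is unavailable).
#' @seealso [encodeRecord()], [decodeImage()]
#' @export
setClass("EncodedImage",
         representation(pixels = "array",
                        slotBounds = "integer",
                        palette = "matrix",
                        sourceVector = "numeric"))

setValidity("EncodedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3 || d[3] != 3) return("pixels must be h x w x 3")
  b <- object@slotBounds
  if (b[1] != 0L || b[length(b)] != d[2]) {
    return("slotBounds must start at 0 and end at the image width")
  }
  if (any(diff(b) <= 0)) return("slotBounds must be strictly increasing")
  if (nrow(object@palette) != length(b) - 1L) {
    return("palette must have one colour per slot")
  }
  if (min(object@pixels) < 0 || max(object@pixels) > 255) {
    return("pixel values must lie in [0, 255]")
  }
  TRUE
})

#' EvaluationReport: pooled held-out predictions and derived metrics
#'
#' The result of a leave-one-out cross-validation run: one held-out
#' positive-class probability per sample, the confusion counts at the decision
#' threshold, threshold-free metrics (ROC/AUC, Brier score), the ROC polyline
#' and the calibration bins, plus per-fold bookkeeping sufficient to audit the
#' protocol for leakage.
#'
#' @slot probs Held-out positive-class probabilities, one per sample.
#' @slot labels True 0/1 labels.
#' @slot threshold Decision threshold used for the confusion counts.
#' @slot confusion Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @slot metrics Named list: `precision`, `recall`, `f1`, `auc`, `brier`.
#' @slot rocPoints `data.frame` with columns `fpr`, `tpr`.
#' @slot calibration `data.frame` with columns `meanPred`, `obsFreq`, `count`.
#' @slot folds Per-fold bookkeeping (`data.frame`: fold, held-out index, seed,
#'   training-set size).
#' @slot details Free-form list of audit material (e.g. per-fold training
#'   indices recorded by the stacking protocol).
#' @seealso [runLoocv()], [stackLoocv()]
#' @export
setClass("EvaluationReport",
         representation(probs = "numeric",
                        labels = "integer",
                        threshold = "numeric",
                        confusion = "integer",
                        metrics = "list",
                        rocPoints = "data.frame",
                        calibration = "data.frame",
                        folds = "data.frame",
                        details = "list"))

setValidity("EvaluationReport", function(object) {
  n <- length(object@probs)
  if (length(object@labels) != n) return("one label per probability required")
  if (any(object@probs < 0 | object@probs > 1)) {
    return("probabilities must lie in [0, 1]")
  }
  if (!all(names(object@confusion) == c("TP", "FP", "TN", "FN"))) {
    return("confusion must be named TP, FP, TN, FN")
  }
  if (sum(object@confusion) != n) return("confusion counts must sum to n")
  ms <- unlist(object@metrics[c("precision", "recall", "f1", "auc", "brier")])
  if (any(ms < 0 | ms > 1)) return("metrics must lie in [0, 1]")
  rp <- object@rocPoints
  if (nrow(rp) && (is.unsorted(rp$fpr) || is.unsorted(rp$tpr))) {
    return("ROC points must be monotone non-decreasing in both coordinates")
  }
  TRUE
})
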