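#' Number of features declared by a schema or dataset
#'
#' @param x A [FeatureSchema-class] or [TabularDataset-class].
#' @return Integer count of features `m`.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Feature names in encoding order
#'
#' @param x A [FeatureSchema-class] or [TabularDataset-class].
#' @return Character vector of feature names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Feature value matrix of a dataset
#'
#' @param x A [TabularDataset-class].
#' @return The `n x m` numeric value matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Binary labels of a dataset or report
#'
#' @param x A [TabularDataset-class] or [EvaluationReport-class].
#' @return Integer 0/1 vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Number of records
#'
#' @param x A [TabularDataset-class].
#' @return Integer record count `n`.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Pixel raster of an encoded image
#'
#' @param x An [EncodedImage-class].
#' @return Numeric `h x w x 3` array on the 0..255 scale.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Slot boundaries of an encoded image
#'
#' @param x An [EncodedImage-class].
#' @return Integer vector of `m + 1` x-coordinates.
#' @export
setGeneric("slotBoundaries", function(x) standardGeneric("slotBoundaries"))

#' Held-out probabilities of an evaluation report
#'
#' @param x An [EvaluationReport-class].
#' @return Numeric vector of positive-class probabilities.
#' @export
setGeneric("heldOutProbs", function(x) standardGeneric("heldOutProbs"))

#' Pooled metrics of an evaluation report
#'
#' @param x An [EvaluationReport-class].
#' @return Named list with `precision`, `recall`, `f1`, `auc`, `brier`.
#' @export
setGeneric("reportMetrics", function(x) standardGeneric("reportMetrics"))
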