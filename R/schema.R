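#' Declare one feature
#'
#' @param name Feature name.
#' @param kind `"continuous"` or `"ordinal"`.
#' @param domainMin,domainMax Domain bounds; for ordinal features these are
#'   integer category bounds (symptom scores run 0 to 5).
#' @param colorIndex Non-negative integer selecting the feature's display
#'   colour; defaults are assigned by [featureSchema()] in declaration order.
#' @return A one-row `data.frame` suitable for [featureSchema()].
#' @export
#' @examples
#' featureSpec("PSA", "continuous", 0, 200)
featureSpec <- function(name, kind = c("continuous", "ordinal"),
                        domainMin, domainMax, colorIndex = NA_integer_) {
  kind <- match.arg(kind)
  data.frame(name = as.character(name), kind = kind,
             domainMin = as.numeric(domainMin),
             domainMax = as.numeric(domainMax),
             colorIndex = as.integer(colorIndex),
             stringsAsFactors = FALSE)
}

#' Build a feature schema
#'
#' @param ... One or more [featureSpec()] rows, in encoding order.
#' @return A validated [FeatureSchema-class].
#' @export
#' @examples
#' sch <- featureSchema(
#'   featureSpec("PSA", "continuous", 0, 200),
#'   featureSpec("Urgency", "ordinal", 0, 5))
#' nFeatures(sch)
featureSchema <- function(...) {
  f <- do.call(rbind, list(...))
  if (is.null(f) || nrow(f) < 1) stop("a schema needs at least one feature")
  if (all(is.na(f$colorIndex))) {
    f$colorIndex <- seq_len(nrow(f)) - 1L
  }
  rownames(f) <- NULL
  new("FeatureSchema", features = f)
}

#' The nine-feature prostate screening schema
#'
#' PSA (ng/mL) and age are continuous; the seven lower-urinary-tract symptom
#' frequencies (IPSS-style questionnaire items) are ordinal on a 0--5 scale,
#' 0 = never and 5 = always.
#'
#' @return A [FeatureSchema-class] with nine features in encoding order.
#' @export
#' @examples
#' featureNames(prostateSchema())
prostateSchema <- function() {
  ord <- function(nm) featureSpec(nm, "ordinal", 0, 5)
  featureSchema(
    featureSpec("PSA", "continuous", 0, 200),
    featureSpec("Age", "continuous", 40, 95),
    ord("IEBladder"),
    ord("UrinateAgain"),
    ord("Intermittency"),
    ord("Urgency"),
    ord("Nocturia"),
    ord("Straining"),
    ord("WeakUrine"))
}

#' Construct a tabular dataset
#'
#' @param schema A [FeatureSchema-class].
#' @param values `n x m` numeric matrix (or data.frame) in schema column order.
#' @param labels 0/1 vector, 1 = positive class (carcinoma).
#' @return A validated [TabularDataset-class].
#' @export
tabularDataset <- function(schema, values, labels) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  colnames(v) <- featureNames(schema)
  new("TabularDataset", schema = schema, values = v,
      labels = as.integer(labels))
}

#' @rdname nFeatures
setMethod("nFeatures", "FeatureSchema", function(x) nrow(x@features))
#' @rdname nFeatures
setMethod("nFeatures", "TabularDataset", function(x) nFeatures(x@schema))
#' @rdname featureNames
setMethod("featureNames", "FeatureSchema", function(x) x@features$name)
#' @rdname featureNames
setMethod("featureNames", "TabularDataset", function(x) featureNames(x@schema))
#' @rdname featureValues
setMethod("featureValues", "TabularDataset", function(x) x@values)
#' @rdname classLabels
setMethod("classLabels", "TabularDataset", function(x) x@labels)
#' @rdname classLabels
setMethod("classLabels", "EvaluationReport", function(x) x@labels)
#' @rdname nSamples
setMethod("nSamples", "TabularDataset", function(x) nrow(x@values))

setMethod("show", "FeatureSchema", function(object) {
  f <- object@features
  cat("FeatureSchema with", nrow(f), "features\n")
  cat(sprintf("  %-14s %-11s domain [%g, %g]\n",
              f$name, f$kind, f$domainMin, f$domainMax), sep = "")
})

setMethod("show", "TabularDataset", function(object) {
  cat("TabularDataset:", nSamples(object), "records x",
      nFeatures(object), "features\n")
  tab <- table(factor(object@labels, levels = c(0, 1)))
  cat("  labels: ", tab[["0"]], " negative / ", tab[["1"]], " positive\n",
      sep = "")
})

#' Extract the schema of a dataset
#'
#' @param x A [TabularDataset-class].
#' @return The [FeatureSchema-class].
#' @export
datasetSchema <- function(x) x@schema

#' Subset a dataset by record indices
#'
#' @param x A [TabularDataset-class].
#' @param idx Integer record indices to keep.
#' @return A [TabularDataset-class] with the selected records, row order
#'   preserved.
#' @export
subsetDataset <- function(x, idx) {
  tabularDataset(x@schema, x@values[idx, , drop = FALSE], x@labels[idx])
}
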