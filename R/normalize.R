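#' Fit per-feature min-max scaling
#'
#' Learns the per-column minimum and maximum of the training values, so that
#' [applyNormalizer()] can scale every feature into `[0, 1]` before image
#' encoding. With `useDeclaredBounds = TRUE`, ordinal features are fitted to
#' their declared domain (0--5 for the symptom scores) instead of the observed
#' range, which keeps the scaling identical across cross-validation refits.
#'
#' A constant column (observed min equal to max) triggers a warning; such a
#' feature always normalizes to 0.
#'
#' @param dataset A [TabularDataset-class].
#' @param useDeclaredBounds Fit ordinal features to their declared domain
#'   bounds rather than the observed min/max. Default `FALSE`.
#' @return A [Normalizer-class].
#' @export
#' @examples
#' ds <- generateCohort(defaultProstateProfile(), seed = 1)
#' fitNormalizer(ds)
fitNormalizer <- function(dataset, useDeclaredBounds = FALSE) {
  stopifnot(is(dataset, "TabularDataset"))
  v <- dataset@values
  f <- dataset@schema@features
  lo <- apply(v, 2, min)
  hi <- apply(v, 2, max)
  if (useDeclaredBounds) {
    ord <- f$kind == "ordinal"
    lo[ord] <- f$domainMin[ord]
    hi[ord] <- f$domainMax[ord]
  }
  const <- lo == hi
  if (any(const)) {
    warning("constant feature(s) ", paste(f$name[const], collapse = ", "),
            ": will normalize to 0")
  }
  new("Normalizer", fittedMin = unname(lo), fittedMax = unname(hi),
      featureNames = f$name)
}

#' Min-max normalize records
#'
#' Scales each feature as `(x - fittedMin) / (fittedMax - fittedMin)` and clips
#' the result into `[0, 1]`. Values outside the fitted range (unseen test
#' values) are clipped with a warning; constant features map to 0.
#'
#' @param x A numeric record of length `m`, or an `n x m` matrix of records.
#' @param normalizer A [Normalizer-class] from [fitNormalizer()].
#' @return Normalized values in `[0, 1]`, same shape as `x`.
#' @export
applyNormalizer <- function(x, normalizer) {
  stopifnot(is(normalizer, "Normalizer"))
  vec <- is.null(dim(x))
  m <- matrix(if (vec) x else as.matrix(x), ncol = length(normalizer@featureNames))
  if (ncol(m) != length(normalizer@featureNames) && vec) {
    stop("record length must equal the number of fitted features")
  }
  if (any(!is.finite(m))) {
    bad <- which(apply(!is.finite(m), 2, any))
    stop("non-finite value in feature(s): ",
         paste(normalizer@featureNames[bad], collapse = ", "))
  }
  lo <- normalizer@fittedMin
  hi <- normalizer@fittedMax
  rng <- hi - lo
  out <- sweep(sweep(m, 2, lo, "-"), 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  if (any(out < 0 | out > 1)) {
    warning("value(s) outside the fitted range were clipped to [0, 1]")
    out <- clamp(out, 0, 1)
  }
  if (vec) drop(out) else {
    colnames(out) <- normalizer@featureNames
    out
  }
}

setMethod("show", "Normalizer", function(object) {
  cat("Normalizer for", length(object@featureNames), "features\n")
  cat(sprintf("  %-14s [%g, %g]\n", object@featureNames,
              object@fittedMin, object@fittedMax), sep = "")
})
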