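#' Available CNN backbones
#'
#' Backbones are pluggable frozen feature extractors. The bundled `"tiny"`
#' backbone is a small randomly-initialized convolutional extractor that
#' requires no download and no GPU; it exists so the whole pipeline — resize,
#' channel normalization, frozen convolutional features, trainable head — runs
#' anywhere and is fully seeded.
#'
#' @return Character vector of backbone identifiers.
#' @export
availableBackbones <- function() c("tiny")

#' Construct the bundled tiny convolutional backbone
#'
#' A single convolutional layer of `nFilters` random 3 x 3 x 3 filters
#' (He-scaled, drawn once from `seed`) followed by ReLU and spatial average
#' pooling on a `rowBins x colBins` grid. Inputs are resized to
#' `inputHeight x inputWidth` and channel-normalized with the backbone's
#' fixed statistics before convolution. The backbone is frozen: its weights
#' are never updated by training.
#'
#' The pooling grid is wider than tall because the bar encoding varies
#' horizontally — bar width carries the feature value while the vertical
#' direction is redundant.
#'
#' @param inputHeight,inputWidth Expected input size in pixels.
#' @param nFilters Number of convolution filters.
#' @param rowBins,colBins Average-pooling grid; the feature dimension is
#'   `nFilters * rowBins * colBins`.
#' @param seed Seed for the filter draw (fixed default so two calls give
#'   bit-identical backbones).
#' @return A list of class `"Backbone"`.
#' @export
#' @examples
#' b <- tinyBackbone()
#' b$featureDim
tinyBackbone <- function(inputHeight = 30L, inputWidth = 40L, nFilters = 8L,
                         rowBins = 2L, colBins = 10L, seed = 101L) {
  k <- 3L
  weights <- withSeed(seed, {
    array(stats::rnorm(k * k * 3 * nFilters, sd = sqrt(2 / (k * k * 3))),
          c(k, k, 3, nFilters))
  })
  # precomputed mean-pooling operator over the activation grid
  oh <- as.integer(inputHeight) - k + 1L
  ow <- as.integer(inputWidth) - k + 1L
  rBin <- ceiling(seq_len(oh) / oh * rowBins)
  cBin <- ceiling(seq_len(ow) / ow * colBins)
  g <- rep(rBin, times = ow) + (rep(cBin, each = oh) - 1L) * rowBins
  pool <- matrix(0, rowBins * colBins, oh * ow)
  pool[cbind(g, seq_along(g))] <- 1
  pool <- pool / rowSums(pool)
  structure(list(identifier = "tiny",
                 inputSize = c(as.integer(inputHeight), as.integer(inputWidth)),
                 kernelSize = k,
                 weights = weights,
                 bias = numeric(nFilters),
                 channelMean = rep(0.5, 3), channelSd = rep(0.25, 3),
                 rowBins = as.integer(rowBins), colBins = as.integer(colBins),
                 pool = pool,
                 featureDim = as.integer(nFilters * rowBins * colBins),
                 frozen = TRUE),
            class = "Backbone")
}

#' Look up a backbone by identifier
#'
#' @param identifier A backbone name; see [availableBackbones()].
#' @param ... Passed to the backbone constructor.
#' @return A `"Backbone"` object.
#' @export
getBackbone <- function(identifier, ...) {
  if (!identifier %in% availableBackbones()) {
    stop("unknown backbone '", identifier, "'; available: ",
         paste(availableBackbones(), collapse = ", "))
  }
  switch(identifier, tiny = tinyBackbone(...))
}

# Resize an h x w x 3 raster. EBImage::resize() addresses dim1 through its
# `w` argument, so the roles are swapped relative to row-major rasters.
resizeRaster <- function(px, height, width) {
  if (dim(px)[1] == height && dim(px)[2] == width) return(px)
  EBImage::resize(px, w = height, h = width)
}

#' Extract frozen backbone features from an image
#'
#' Resizes the image to the backbone's expected input size, normalizes the
#' channels with the backbone's statistics, applies the frozen convolution +
#' ReLU and grid-average-pools the activation map into a fixed-length feature
#' vector.
#'
#' @param backbone A `"Backbone"` object.
#' @param img An [EncodedImage-class] or `h x w x 3` raster on 0..255.
#' @return Numeric feature vector of length `backbone$featureDim`.
#' @export
backboneFeatures <- function(backbone, img) {
  stopifnot(inherits(backbone, "Backbone"))
  px <- asRaster(img) / 255
  px <- resizeRaster(px, backbone$inputSize[1], backbone$inputSize[2])
  for (c in 1:3) {
    px[, , c] <- (px[, , c] - backbone$channelMean[c]) / backbone$channelSd[c]
  }
  k <- backbone$kernelSize
  h <- dim(px)[1]; w <- dim(px)[2]
  oh <- h - k + 1L; ow <- w - k + 1L
  # im2col: one column per (kernel row, kernel col, channel)
  patches <- matrix(0, oh * ow, k * k * 3)
  col <- 1L
  for (c in 1:3) {
    for (dc in 0:(k - 1L)) {
      for (dr in 0:(k - 1L)) {
        patches[, col] <- as.vector(px[dr + seq_len(oh), dc + seq_len(ow), c])
        col <- col + 1L
      }
    }
  }
  wMat <- matrix(backbone$weights, k * k * 3, dim(backbone$weights)[4])
  act <- pmax(sweep(patches %*% wMat, 2, backbone$bias, "+"), 0)
  # grid average pooling via the precomputed operator
  as.numeric(backbone$pool %*% act)
}
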