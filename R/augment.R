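#' Augmentation configuration
#'
#' Sampling ranges for the stochastic augmentation pipeline: elastic distortion
#' (deformation strength `alpha`, field smoothness `sigma`) followed by
#' morphological bar dilation/erosion applied with random probabilities in a
#' random order with a random rectangular structuring element. The defaults are
#' the ranges used for the 640 x 480 prostate images: `alpha` in [40, 60],
#' `sigma` in [3, 5], both operator probabilities in [0.7, 0.8], and a
#' structuring element of size 2 x 5 or smaller. When rendering at a smaller
#' width, scale `alpha` and `sigma` by the same factor to obtain geometrically
#' equivalent distortions.
#'
#' @param alphaRange Numeric interval for the displacement scaling factor
#'   (pixels); `alpha = 0` leaves the image untouched.
#' @param sigmaRange Numeric interval (pixels) for the standard deviation of
#'   the Gaussian filter applied to the displacement field; low values give
#'   localized ripples, high values smooth waves.
#' @param pDilateRange,pErodeRange Probability intervals for applying bar
#'   dilation / bar erosion.
#' @param seMaxHeight,seMaxWidth Upper bounds of the rectangular structuring
#'   element; each operator samples its own height in `1..seMaxHeight` and
#'   width in `1..seMaxWidth`. Wider-than-tall defaults because bars vary
#'   horizontally: width encodes the feature value.
#' @param interpolation `"bilinear"` (training default) or `"nearest"`, which
#'   preserves the exact colour inventory of the input.
#' @return A list of class `"AugmentationConfig"`.
#' @export
augmentationConfig <- function(alphaRange = c(40, 60),
                               sigmaRange = c(3, 5),
                               pDilateRange = c(0.7, 0.8),
                               pErodeRange = c(0.7, 0.8),
                               seMaxHeight = 2L, seMaxWidth = 5L,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(alphaRange) == 2, alphaRange[1] >= 0, diff(alphaRange) >= 0,
            length(sigmaRange) == 2, sigmaRange[1] > 0, diff(sigmaRange) >= 0,
            all(pDilateRange >= 0 & pDilateRange <= 1),
            all(pErodeRange >= 0 & pErodeRange <= 1),
            diff(pDilateRange) >= 0, diff(pErodeRange) >= 0,
            seMaxHeight >= 1, seMaxWidth >= 1)
  structure(list(alphaRange = alphaRange, sigmaRange = sigmaRange,
                 pDilateRange = pDilateRange, pErodeRange = pErodeRange,
                 seMaxHeight = as.integer(seMaxHeight),
                 seMaxWidth = as.integer(seMaxWidth),
                 interpolation = interpolation),
            class = "AugmentationConfig")
}

# Coerce EncodedImage or raw array to an h x w x 3 raster on 0..255.
asRaster <- function(img) {
  if (is(img, "EncodedImage")) return(img@pixels)
  stopifnot(is.array(img), length(dim(img)) == 3, dim(img)[3] == 3)
  img
}

# Elastic distortion using the caller's RNG stream.
elasticCore <- function(px, alpha, sigma, interpolation) {
  h <- dim(px)[1]; w <- dim(px)[2]
  dy <- matrix(stats::runif(h * w, -1, 1), h, w)
  dx <- matrix(stats::runif(h * w, -1, 1), h, w)
  dy <- .gaussSmooth(dy, sigma) * alpha
  dx <- .gaussSmooth(dx, sigma) * alpha
  .warpRaster(px, dy, dx, if (interpolation == "nearest") 1L else 0L)
}

#' Elastic distortion of a bar image
#'
#' Warps the image by a smoothed random displacement field: per-axis
#' uniform `[-1, 1]` noise is Gaussian-filtered with standard deviation
#' `sigma` and scaled by `alpha`, and pixels are resampled at the displaced
#' coordinates with reflected borders. `alpha = 0` reproduces the input
#' exactly; a fixed seed gives a fixed distortion.
#'
#' @param img An [EncodedImage-class] or `h x w x 3` array on 0..255.
#' @param alpha Displacement scaling factor, `>= 0`.
#' @param sigma Gaussian standard deviation, `> 0`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   consumed.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return An `h x w x 3` array on the 0..255 scale.
#' @export
elasticDistort <- function(img, alpha, sigma, seed = NULL,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (sigma <= 0) stop("sigma must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  px <- asRaster(img)
  if (is.null(seed)) {
    elasticCore(px, alpha, sigma, interpolation)
  } else {
    withSeed(seed, elasticCore(px, alpha, sigma, interpolation))
  }
}

# Rectangular grayscale min/max filter with reflected borders; offsets are
# centred (rounded down for even sizes). EBImage's erode/dilate are
# binary-only, hence this compiled implementation.
rectFilter <- function(px, seHeight, seWidth, op = c("min", "max")) {
  op <- match.arg(op)
  .rectFilter(px, as.integer(seHeight), as.integer(seWidth),
              if (op == "min") 0L else 1L)
}

#' Bar dilation: expand the coloured bars
#'
#' Grayscale minimum filter over a rectangular structuring element. On a
#' white-background image this expands the coloured (darker) bar regions, so
#' the count of non-background pixels never decreases.
#'
#' @param img An [EncodedImage-class] or `h x w x 3` array on 0..255.
#' @param seHeight,seWidth Structuring-element size; a 1 x 1 element is the
#'   identity.
#' @return An `h x w x 3` array.
#' @export
barDilate <- function(img, seHeight, seWidth) {
  rectFilter(asRaster(img), seHeight, seWidth, "min")
}

#' Bar erosion: shrink the coloured bars
#'
#' Grayscale maximum filter over a rectangular structuring element: the
#' white background grows into the bars, so the count of non-background pixels
#' never increases.
#'
#' @inheritParams barDilate
#' @return An `h x w x 3` array.
#' @export
barErode <- function(img, seHeight, seWidth) {
  rectFilter(asRaster(img), seHeight, seWidth, "max")
}

# Morphology step using the caller's RNG stream. Draw order is fixed
# (op order, both gate variables, both SE sizes) so the stream is identical
# whatever fires.
morphologyCore <- function(px, pDilate, pErode, seMaxHeight, seMaxWidth) {
  dilateFirst <- stats::runif(1) < 0.5
  uDilate <- stats::runif(1)
  uErode <- stats::runif(1)
  seD <- c(sample.int(seMaxHeight, 1), sample.int(seMaxWidth, 1))
  seE <- c(sample.int(seMaxHeight, 1), sample.int(seMaxWidth, 1))
  doDilate <- function(x) if (uDilate <= pDilate) barDilate(x, seD[1], seD[2]) else x
  doErode <- function(x) if (uErode <= pErode) barErode(x, seE[1], seE[2]) else x
  if (dilateFirst) doErode(doDilate(px)) else doDilate(doErode(px))
}

#' Random morphological augmentation
#'
#' With probability `pDilate` applies bar dilation and with probability
#' `pErode` bar erosion, in a uniformly random order, each with its own
#' independently sampled rectangular structuring element. Depending on the
#' draws the image undergoes dilation only, erosion only, closing
#' (dilation then erosion) or opening (erosion then dilation).
#'
#' @param img An [EncodedImage-class] or `h x w x 3` array on 0..255.
#' @param pDilate,pErode Application probabilities in `[0, 1]`.
#' @param seMaxHeight,seMaxWidth Upper bounds for the structuring element.
#' @param seed Optional integer seed; `NULL` consumes the current RNG stream.
#' @return An `h x w x 3` array.
#' @export
randomMorphology <- function(img, pDilate, pErode,
                             seMaxHeight = 2L, seMaxWidth = 5L, seed = NULL) {
  stopifnot(pDilate >= 0, pDilate <= 1, pErode >= 0, pErode <= 1)
  px <- asRaster(img)
  if (pDilate == 0 && pErode == 0) return(px)
  run <- function() morphologyCore(px, pDilate, pErode,
                                   as.integer(seMaxHeight),
                                   as.integer(seMaxWidth))
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' One random augmentation of a bar image
#'
#' Samples `alpha`, `sigma`, `pDilate` and `pErode` uniformly from their
#' configured ranges, then applies elastic distortion followed by random
#' morphology. Output dimensions equal the input's; a fixed seed makes the
#' augmentation bit-reproducible.
#'
#' @param img An [EncodedImage-class] or `h x w x 3` array on 0..255.
#' @param config An [augmentationConfig()].
#' @param seed Optional integer seed; `NULL` consumes the current RNG stream.
#' @return An `h x w x 3` array.
#' @export
augmentImage <- function(img, config = augmentationConfig(), seed = NULL) {
  stopifnot(inherits(config, "AugmentationConfig"))
  px <- asRaster(img)
  run <- function() {
    alpha <- stats::runif(1, config$alphaRange[1], config$alphaRange[2])
    sigma <- stats::runif(1, config$sigmaRange[1], config$sigmaRange[2])
    pd <- stats::runif(1, config$pDilateRange[1], config$pDilateRange[2])
    pe <- stats::runif(1, config$pErodeRange[1], config$pErodeRange[2])
    out <- elasticCore(px, alpha, sigma, config$interpolation)
    morphologyCore(out, pd, pe, config$seMaxHeight, config$seMaxWidth)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Augment a training set k times
#'
#' Returns the original images plus `k` fresh augmentations of each, with
#' labels replicated accordingly: `n` images become `n * (k + 1)`. Each
#' augmentation draws its parameters from a seed derived deterministically
#' from `masterSeed`, the image index and the replicate index, so the whole
#' augmented set is bit-reproducible and per-fold augmentation streams are
#' independent.
#'
#' @param images List of [EncodedImage-class] objects or rasters.
#' @param labels 0/1 labels, one per image.
#' @param k Number of augmentations per image, `k >= 0`; `k = 1` doubles the
#'   training data.
#' @param config An [augmentationConfig()].
#' @param masterSeed Integer master seed.
#' @return List with `images` (length `n * (k + 1)`: originals first, then
#'   augmentations in image-major order) and `labels`.
#' @export
#' @examples
#' imgs <- lapply(1:3, function(i) encodeRecord(rep(0.5, 2), encodingConfig(16, 12)))
#' aug <- augmentTrainingSet(imgs, c(0, 1, 1), k = 2,
#'                           config = augmentationConfig(c(1, 2), c(0.8, 1)),
#'                           masterSeed = 7)
#' length(aug$images)  # 9
augmentTrainingSet <- function(images, labels, k,
                               config = augmentationConfig(), masterSeed = 1L) {
  if (k < 0) stop("k must be >= 0")
  n <- length(images)
  stopifnot(length(labels) == n)
  rasters <- lapply(images, asRaster)
  outImages <- rasters
  outLabels <- as.integer(labels)
  if (k > 0) {
    extra <- vector("list", n * k)
    pos <- 1L
    for (i in seq_len(n)) {
      for (r in seq_len(k)) {
        extra[[pos]] <- augmentImage(rasters[[i]], config,
                                     seed = deriveSeed(masterSeed, i, r))
        pos <- pos + 1L
      }
    }
    outImages <- c(outImages, extra)
    outLabels <- c(outLabels, rep(as.integer(labels), each = k))
  }
  list(images = outImages, labels = outLabels)
}
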