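#' Encoding configuration
#'
#' Geometry and colours for the bar-chart image representation. Records are
#' rendered as `m` left-anchored, full-height vertical bars, one per feature,
#' each inside an equal-width slot of the image.
#'
#' @param width,height Image size in pixels. The defaults (640 x 480) are the
#'   size used for the prostate cohort experiments; smaller rasters encode the
#'   same information at coarser width quantization.
#' @param background RGB background colour (0..255), white by default.
#' @param palette Optional `m x 3` integer matrix of per-feature colours; by
#'   default [makePalette()] assigns maximally-distinct hues in schema order.
#' @return A list of class `"EncodingConfig"`.
#' @export
encodingConfig <- function(width = 640L, height = 480L,
                           background = c(255L, 255L, 255L),
                           palette = NULL) {
  stopifnot(width >= 1, height >= 1, length(background) == 3)
  if (!is.null(palette)) {
    palette <- as.matrix(palette)
    if (ncol(palette) != 3) stop("palette must be an m x 3 RGB matrix")
    if (anyDuplicated(palette)) stop("palette colours must be pairwise distinct")
    if (any(apply(palette, 1, function(r) all(r == background)))) {
      stop("palette colours must differ from the background")
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = as.integer(background), palette = palette),
            class = "EncodingConfig")
}

#' Deterministic distinct colour palette
#'
#' Evenly spaced hues at fixed saturation and value, so any number of features
#' get pairwise-distinct colours, none equal to the white background, and the
#' same call always returns the same palette.
#'
#' @param m Number of colours (features), `m >= 1`.
#' @return Integer `m x 3` matrix of RGB colours on the 0..255 scale.
#' @export
#' @examples
#' makePalette(9)
makePalette <- function(m) {
  if (m < 1) stop("m must be >= 1")
  hues <- (seq_len(m) - 1) / m
  cols <- grDevices::hsv(h = hues, s = 0.78, v = 0.86)
  t(grDevices::col2rgb(cols))
}

#' Slot boundaries of the bar layout
#'
#' Divides an image of width `w` into `m` equal slots of real-valued width
#' `b = w / m`, returning the `m + 1` integer boundaries
#' `round(i * w / m)` (half away from zero). Integer slot widths differ by at
#' most one pixel and always sum to `w`.
#'
#' @param w Image width in pixels, `w >= m`.
#' @param m Number of features.
#' @return Integer vector of `m + 1` x-coordinates, first 0, last `w`.
#' @export
#' @examples
#' slotBounds(7, 3)    # c(0, 2, 5, 7)
#' diff(slotBounds(640, 9))
slotBounds <- function(w, m) {
  if (m < 1) stop("m must be >= 1")
  if (w < m) stop("image width must be >= number of features")
  as.integer(roundHalfUp(0:m * (w / m)))
}

#' Encode a normalized record as a bar image
#'
#' Renders a record already scaled into `[0, 1]` (see [applyNormalizer()]) as
#' an image of `m` coloured vertical bars. Bar `i` is left-anchored in slot
#' `i`, spans the full image height, and has width
#' `round(v[i] * slotWidth[i])`: a feature at its maximum normalized value 1
#' fills its whole slot, while a value small enough to round to zero width
#' leaves the slot empty — absence is information.
#'
#' @param v Numeric vector in `[0, 1]^m`.
#' @param config An [encodingConfig()].
#' @return An [EncodedImage-class].
#' @export
#' @examples
#' img <- encodeRecord(rep(0.5, 9), encodingConfig(90, 30))
#' slotBoundaries(img)
encodeRecord <- function(v, config = encodingConfig()) {
  m <- length(v)
  if (m < 1) stop("v must have at least one element")
  if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
    stop("v must lie in [0, 1]; normalize the record first")
  }
  pal <- config$palette
  if (is.null(pal)) pal <- makePalette(m)
  if (nrow(pal) != m) stop("palette length must match the number of features")
  bounds <- slotBounds(config$width, m)
  h <- config$height
  px <- array(0, c(h, config$width, 3))
  for (c in 1:3) px[, , c] <- config$background[c]
  for (i in seq_len(m)) {
    sw <- bounds[i + 1] - bounds[i]
    bw <- as.integer(roundHalfUp(v[i] * sw))
    if (bw > 0) {
      cols <- (bounds[i] + 1):(bounds[i] + bw)
      for (c in 1:3) px[, cols, c] <- pal[i, c]
    }
  }
  new("EncodedImage", pixels = px, slotBounds = bounds,
      palette = pal, sourceVector = as.numeric(v))
}

#' Encode every record of a dataset
#'
#' Fits (or reuses) a [Normalizer-class] and encodes each record with
#' [encodeRecord()].
#'
#' @param dataset A [TabularDataset-class].
#' @param config An [encodingConfig()].
#' @param normalizer Optional pre-fitted [Normalizer-class]; fitted on
#'   `dataset` when `NULL`.
#' @return A list of [EncodedImage-class] objects, one per record.
#' @export
encodeDataset <- function(dataset, config = encodingConfig(),
                          normalizer = NULL) {
  if (is.null(normalizer)) normalizer <- fitNormalizer(dataset)
  vn <- applyNormalizer(dataset@values, normalizer)
  lapply(seq_len(nrow(vn)), function(i) encodeRecord(vn[i, ], config))
}

#' Decode a bar image back to its normalized record
#'
#' Inverse of [encodeRecord()] for unaugmented images: per slot, the fraction
#' of pixel columns that are not background. The reconstruction error is at
#' most one pixel of bar width, i.e. `1 / slotWidth` per feature.
#'
#' @param img An [EncodedImage-class] produced by [encodeRecord()].
#' @param config The [encodingConfig()] used for encoding.
#' @return Numeric vector in `[0, 1]^m`.
#' @export
decodeImage <- function(img, config = encodingConfig()) {
  stopifnot(is(img, "EncodedImage"))
  px <- img@pixels
  bounds <- img@slotBounds
  m <- length(bounds) - 1L
  bg <- config$background
  v <- numeric(m)
  for (i in seq_len(m)) {
    cols <- (bounds[i] + 1):bounds[i + 1]
    slot <- px[, cols, , drop = FALSE]
    nb <- slot[, , 1] != bg[1] | slot[, , 2] != bg[2] | slot[, , 3] != bg[3]
    painted <- which(apply(nb, 2, any))
    if (length(painted)) {
      sub <- matrix(slot[, painted, ], ncol = 3)
      sub <- sub[rowSums(sub != matrix(bg, nrow(sub), 3, byrow = TRUE)) > 0, ,
                 drop = FALSE]
      ok <- sub[, 1] == img@palette[i, 1] & sub[, 2] == img@palette[i, 2] &
        sub[, 3] == img@palette[i, 3]
      if (!all(ok)) stop("slot ", i, " contains colours not in the palette")
    }
    v[i] <- length(painted) / length(cols)
  }
  v
}

#' @rdname pixels
setMethod("pixels", "EncodedImage", function(x) x@pixels)
#' @rdname slotBoundaries
setMethod("slotBoundaries", "EncodedImage", function(x) x@slotBounds)

setMethod("show", "EncodedImage", function(object) {
  d <- dim(object@pixels)
  cat("EncodedImage:", d[2], "x", d[1], "pixels,",
      length(object@slotBounds) - 1L, "bar slots\n")
})

#' Write a raster to a PNG file
#'
#' PNG is used because it is lossless: augmentation monotonicity and colour
#' identifiability rely on exact pixel values.
#'
#' @param img An [EncodedImage-class] or an `h x w x 3` array on 0..255.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(img, path) {
  px <- if (is(img, "EncodedImage")) img@pixels else img
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read a raster from a PNG file
#'
#' @param path PNG file path.
#' @return Numeric `h x w x 3` array on the 0..255 scale.
#' @export
readImagePNG <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  # PNG samples are 8- or 16-bit, so k/depth * 255 is integer up to rounding
  round(px[, , 1:3, drop = FALSE] * 255, 6)
}
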