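#' Derive a child seed from a master seed
#'
#' Combines a master seed with any number of integer indices through a
#' deterministic multiplicative hash, so that every stage, fold and augmentation
#' replicate of a run gets its own reproducible random stream. The result is
#' always a valid R seed in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param ... Integer indices (e.g. fold number, replicate number).
#' @return A single integer seed.
#' @export
#' @examples
#' deriveSeed(13, 1, 2)
deriveSeed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  mod <- 2147483647  # 2^31 - 1, Mersenne prime
  x <- 0
  for (p in parts) {
    # 48271 is the MINSTD multiplier; kept in double precision, which is
    # exact here because all intermediates stay below 2^53
    x <- (x * 48271 + (p %% mod) + 11) %% mod
  }
  as.integer(x)
}

# Evaluate expr with a temporarily-seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (pixel rounding rule; base round() rounds half
# to even, which would make rasters depend on parity).
roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Count non-background pixels
#'
#' The quantity the morphological operators are contracted on: bar dilation
#' never decreases it, bar erosion never increases it.
#'
#' @param img An `h x w x 3` array on the 0..255 scale (or an
#'   [EncodedImage-class]).
#' @param background RGB background colour.
#' @return Integer count of pixels differing from the background in any
#'   channel.
#' @export
nonBackgroundCount <- function(img, background = c(255, 255, 255)) {
  if (is(img, "EncodedImage")) img <- img@pixels
  stopifnot(length(dim(img)) == 3)
  bg <- aperm(array(background, c(3, dim(img)[1], dim(img)[2])), c(2, 3, 1))
  sum(apply(img != bg, c(1, 2), any))
}

# Structured stage-tagged logging. Collected by runPipeline when a log file is
# configured; otherwise emitted through message() at levels >= the threshold.
t2iLog <- function(stage, msg, level = "INFO") {
  line <- sprintf("[%s] %s: %s", level, stage, msg)
  opt <- getOption("tab2img.logfile", NULL)
  if (!is.null(opt)) cat(line, "\n", file = opt, append = TRUE, sep = "")
  if (identical(getOption("tab2img.verbose", FALSE), TRUE) ||
      level %in% c("WARN", "ERROR")) {
    message(line)
  }
  invisible(line)
}
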