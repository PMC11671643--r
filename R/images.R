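# GrayImage constructors, accessors and range conversions. The package keeps
# two intensity conventions: "unit" ([0,1]) for I/O and error maps, and
# "symmetric" ([-1,1]) for the diffusion arithmetic; the affine conversion
# between them is owned here so the threshold tau has unambiguous semantics.

#' Construct a GrayImage
#'
#' @param pixels Numeric matrix.
#' @param range Intensity convention: `"unit"`, `"symmetric"` or `"free"`.
#' @return A [GrayImage-class].
#' @examples
#' img <- grayImage(matrix(runif(16), 4, 4))
#' @export
grayImage <- function(pixels, range = c("unit", "symmetric", "free")) {
  range <- match.arg(range)
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  new("GrayImage", pixels = pixels, range = range)
}

#' Pixel matrix of an image-like object
#' @param x A [GrayImage-class], [NoiseField-class], [AnomalyMap-class] or
#'   [BinaryMask-class] (or a plain matrix, returned as is).
#' @return Numeric (or logical, for masks) matrix.
#' @export
pixels <- function(x) {
  if (is(x, "GrayImage")) return(x@pixels)
  if (is(x, "NoiseField") || is(x, "AnomalyMap")) return(x@values)
  if (is(x, "BinaryMask")) return(x@values)
  if (is.matrix(x)) return(x)
  stop("no pixel representation for class ", class(x)[1], call. = FALSE)
}

#' Declared intensity range of a GrayImage
#' @param x A [GrayImage-class].
#' @return `"unit"`, `"symmetric"` or `"free"`.
#' @export
rangeTag <- function(x) x@range

#' Convert a unit-range image to the symmetric diffusion range
#' @param x A [GrayImage-class] in unit range.
#' @return A symmetric-range [GrayImage-class] (`2x - 1`).
#' @export
toSymmetric <- function(x) {
  if (x@range == "symmetric") return(x)
  if (x@range != "unit") stop("can only convert a unit-range image", call. = FALSE)
  grayImage(2 * x@pixels - 1, "symmetric")
}

#' Convert a symmetric-range image back to unit range
#' @param x A [GrayImage-class] in symmetric range.
#' @return A unit-range [GrayImage-class] (`(x + 1) / 2`).
#' @export
toUnit <- function(x) {
  if (x@range == "unit") return(x)
  if (x@range != "symmetric") stop("can only convert a symmetric-range image", call. = FALSE)
  grayImage((x@pixels + 1) / 2, "unit")
}

#' Clip an image into a declared range
#' @param x A [GrayImage-class] (any range tag).
#' @param range Target range, `"unit"` or `"symmetric"`.
#' @return A [GrayImage-class] with values clipped into the target range.
#' @export
clipImage <- function(x, range = c("symmetric", "unit")) {
  range <- match.arg(range)
  lim <- if (range == "unit") c(0, 1) else c(-1, 1)
  grayImage(.clamp(x@pixels, lim[1], lim[2]), range)
}

.asPixelMatrix <- function(x) {
  m <- pixels(x)
  storage.mode(m) <- "double"
  m
}
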