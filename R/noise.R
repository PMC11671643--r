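# Corruption-noise generators. Multi-octave simplex noise is the primary
# corruption: its power is concentrated at low spatial frequencies, so the
# diffusion process destroys (and the denoiser learns to repair) structured,
# anomaly-sized regions rather than per-pixel speckle.

#' Simplex noise specification
#'
#' Defaults are the octave parameters used throughout the package:
#' base frequency \eqn{2^{-6}} cycles per pixel (a 64-pixel characteristic
#' scale), 6 octaves, amplitude decay 0.8 per octave.
#'
#' @param baseFrequency Cycles per pixel of the lowest octave.
#' @param octaves Number of octaves N.
#' @param decay Amplitude decay rate gamma in (0, 1].
#' @param seed Integer seed; a spec is a pure recipe, identical specs give
#'   identical fields.
#' @return A [SimplexSpec-class].
#' @examples
#' f <- sampleNoise(simplexSpec(seed = 1), 64, 64)
#' @export
simplexSpec <- function(baseFrequency = 2^-6, octaves = 6L, decay = 0.8,
                        seed = 1L) {
  new("SimplexSpec", baseFrequency = baseFrequency,
      octaves = as.integer(octaves), decay = decay, seed = as.integer(seed))
}

#' Gaussian noise specification (baseline corruption)
#' @param seed Integer seed.
#' @return A [GaussianSpec-class].
#' @export
gaussianSpec <- function(seed = 1L) new("GaussianSpec", seed = as.integer(seed))

# Copy of a spec with a replaced seed (fresh field, same parameters).
.freshSpec <- function(spec, seed) {
  spec@seed <- as.integer(seed)
  spec
}

#' Sample a corruption field from a noise specification
#'
#' @param spec A [SimplexSpec-class] or [GaussianSpec-class].
#' @param height,width Field dimensions in pixels.
#' @return A [NoiseField-class].
#' @export
setGeneric("sampleNoise", function(spec, height, width) standardGeneric("sampleNoise"))

#' @rdname sampleNoise
#' @export
setMethod("sampleNoise", "SimplexSpec", function(spec, height, width) {
  new("NoiseField", values = .simplexMatrix(spec, height, width), spec = spec)
})

#' @rdname sampleNoise
#' @export
setMethod("sampleNoise", "GaussianSpec", function(spec, height, width) {
  new("NoiseField", values = .gaussianMatrix(spec, height, width), spec = spec)
})

.sampleNoiseMatrix <- function(spec, height, width) {
  if (is(spec, "SimplexSpec")) .simplexMatrix(spec, height, width)
  else if (is(spec, "GaussianSpec")) .gaussianMatrix(spec, height, width)
  else stop("unknown noise spec class ", class(spec)[1], call. = FALSE)
}

.simplexMatrix <- function(spec, height, width) {
  if (height < 8L || width < 8L)
    stop("simplex fields need height and width >= 8", call. = FALSE)
  withSeed(spec@seed, {
    perm <- sample(0L:255L)
    perm <- c(perm, perm)  # doubled table avoids index wrapping
    offsets <- matrix(runif(2L * spec@octaves, 0, 4096), spec@octaves, 2L)
    raw <- simplex_octaves_cpp(height, width, spec@baseFrequency,
                               spec@octaves, spec@decay, perm, offsets)
    # Exact per-sample standardization: the diffusion equations assume a
    # zero-mean, unit-variance epsilon.
    s <- stats::sd(raw)
    if (s == 0) stop("degenerate simplex field (zero variance)", call. = FALSE)
    (raw - mean(raw)) / s
  })
}

.gaussianMatrix <- function(spec, height, width) {
  if (height < 1L || width < 1L) stop("dimensions must be >= 1", call. = FALSE)
  withSeed(spec@seed, matrix(rnorm(height * width), height, width))
}

#' Generate a multi-octave simplex noise field
#'
#' Convenience wrapper over [sampleNoise()] for the primary corruption.
#' Octave k contributes `decay^k * simplex(baseFrequency * 2^k)` on a
#' seeded, randomly translated lattice; the sum is standardized to exactly
#' zero mean and unit variance.
#'
#' @param height,width Field dimensions (>= 8).
#' @param spec A [SimplexSpec-class].
#' @return A [NoiseField-class].
#' @export
simplexOctaves <- function(height, width, spec = simplexSpec()) {
  sampleNoise(spec, height, width)
}

#' Generate an i.i.d. standard-normal noise field
#'
#' @param height,width Field dimensions.
#' @param seed Integer seed.
#' @return A [NoiseField-class].
#' @export
gaussianField <- function(height, width, seed = 1L) {
  sampleNoise(gaussianSpec(seed), height, width)
}

#' Mean spectral power below a spatial-frequency cutoff
#'
#' Discrete 2D power spectrum of a field, averaged over all non-DC
#' frequency bins with radial frequency at most `cutoff` (cycles per
#' pixel). Used to verify the low-frequency dominance of simplex octaves
#' over Gaussian noise of equal variance -- the mechanism that tunes the
#' corruption (and hence the detector) towards large, structured anomalies.
#'
#' @param field A [NoiseField-class] or matrix.
#' @param cutoff Radial frequency cutoff in cycles per pixel.
#' @return Mean power over the retained bins.
#' @export
lowFrequencyPower <- function(field, cutoff) {
  m <- .asPixelMatrix(field)
  h <- nrow(m); w <- ncol(m)
  p <- Mod(stats::fft(m))^2 / (h * w)
  fy <- (seq_len(h) - 1) / h; fy <- ifelse(fy > 0.5, fy - 1, fy)
  fx <- (seq_len(w) - 1) / w; fx <- ifelse(fx > 0.5, fx - 1, fx)
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  keep <- fr > 0 & fr <= cutoff
  mean(p[keep])
}
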