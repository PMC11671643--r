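#' @title Core S4 classes
#' @name diffAnomaly-classes
#' @description S4 containers used across the diffusion, noise, segmentation
#'   and data-handling layers.
NULL

# ---- ScheduleTable -----------------------------------------------------

#' Variance schedule of a diffusion chain
#'
#' Per-timestep noise variances \eqn{\beta_t}, signal retentions
#' \eqn{\alpha_t = 1 - \beta_t} and their cumulative product
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s} for a chain of length `steps`.
#'
#' @slot steps Integer chain length T.
#' @slot beta Numeric vector of \eqn{\beta_t}, each in (0, 1).
#' @slot alpha Numeric vector of \eqn{\alpha_t}.
#' @slot alphaBar Numeric vector of \eqn{\bar\alpha_t}, strictly decreasing.
#' @exportClass ScheduleTable
setClass("ScheduleTable",
         representation(steps = "integer", beta = "numeric",
                        alpha = "numeric", alphaBar = "numeric"))

setValidity("ScheduleTable", function(object) {
  msgs <- character()
  n <- object@steps
  if (length(n) != 1L || n < 1L) msgs <- c(msgs, "steps must be a positive integer")
  if (length(object@beta) != n) msgs <- c(msgs, "beta must have length steps")
  if (any(object@beta <= 0 | object@beta >= 1)) msgs <- c(msgs, "all beta must lie in (0, 1)")
  if (any(abs(object@alpha - (1 - object@beta)) > 1e-12))
    msgs <- c(msgs, "alpha must equal 1 - beta")
  if (any(abs(object@alphaBar - cumprod(object@alpha)) > 1e-12))
    msgs <- c(msgs, "alphaBar must be the cumulative product of alpha")
  if (n > 1L && any(diff(object@alphaBar) >= 0))
    msgs <- c(msgs, "alphaBar must be strictly decreasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScheduleTable", function(object) {
  cat(sprintf("ScheduleTable: T = %d, beta in [%g, %g], alphaBar_T = %.4g\n",
              object@steps, object@beta[1], object@beta[object@steps],
              object@alphaBar[object@steps]))
})

# ---- GrayImage ---------------------------------------------------------

#' Single-channel 2D image with a declared intensity convention
#'
#' The unit every stage operates on. `range` declares the intensity
#' convention: `"unit"` ([0, 1], used for I/O, display and error maps),
#' `"symmetric"` ([-1, 1], the scale the diffusion equations run on) or
#' `"free"` (unbounded, e.g. a noised image or an unclipped reconstruction).
#'
#' @slot pixels Numeric H x W matrix.
#' @slot range One of `"unit"`, `"symmetric"`, `"free"`.
#' @exportClass GrayImage
setClass("GrayImage",
         representation(pixels = "matrix", range = "character"))

setValidity("GrayImage", function(object) {
  msgs <- character()
  if (!is.numeric(object@pixels)) msgs <- c(msgs, "pixels must be numeric")
  if (!object@range %in% c("unit", "symmetric", "free"))
    msgs <- c(msgs, "range must be 'unit', 'symmetric' or 'free'")
  tol <- 1e-6
  if (object@range == "unit" &&
      (min(object@pixels) < -tol || max(object@pixels) > 1 + tol))
    msgs <- c(msgs, "unit-range pixels must lie in [0, 1]")
  if (object@range == "symmetric" &&
      (min(object@pixels) < -1 - tol || max(object@pixels) > 1 + tol))
    msgs <- c(msgs, "symmetric-range pixels must lie in [-1, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage %dx%d [%s], intensity range [%.3f, %.3f]\n",
              nrow(object@pixels), ncol(object@pixels), object@range,
              min(object@pixels), max(object@pixels)))
})

setMethod("dim", "GrayImage", function(x) dim(x@pixels))

# ---- DiffusionSample ---------------------------------------------------

#' A partially noised image together with its provenance
#'
#' @slot xt The noised image (range `"free"`).
#' @slot t Integer timestep at which it was produced.
#' @slot eps The noise field consumed by the forward step.
#' @exportClass DiffusionSample
setClass("DiffusionSample",
         representation(xt = "GrayImage", t = "integer", eps = "matrix"))

setMethod("show", "DiffusionSample", function(object) {
  cat(sprintf("DiffusionSample at t = %d (%dx%d)\n", object@t,
              nrow(object@eps), ncol(object@eps)))
})

# ---- Noise specifications ----------------------------------------------

#' Virtual parent of corruption-noise specifications
#' @exportClass NoiseSpec
setClass("NoiseSpec", representation("VIRTUAL"))

#' Multi-octave simplex noise specification
#'
#' Octave k (k = 0..octaves-1) is sampled at spatial frequency
#' `baseFrequency * 2^k` cycles per pixel with amplitude `decay^k`, on a
#' lattice translated by a seeded random offset, and the octave sum is
#' standardized to zero mean and unit variance.
#'
#' @slot baseFrequency Base frequency in cycles per pixel (default 2^-6).
#' @slot octaves Number of octaves N (>= 1).
#' @slot decay Amplitude decay rate gamma in (0, 1].
#' @slot seed Integer seed; the field is a pure function of the spec.
#' @exportClass SimplexSpec
setClass("SimplexSpec", contains = "NoiseSpec",
         representation(baseFrequency = "numeric", octaves = "integer",
                        decay = "numeric", seed = "integer"))

setValidity("SimplexSpec", function(object) {
  msgs <- character()
  if (object@octaves < 1L) msgs <- c(msgs, "octaves must be >= 1")
  if (object@baseFrequency <= 0) msgs <- c(msgs, "baseFrequency must be > 0")
  if (object@decay <= 0 || object@decay > 1) msgs <- c(msgs, "decay must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Gaussian (i.i.d. standard normal) noise specification
#' @slot seed Integer seed.
#' @exportClass GaussianSpec
setClass("GaussianSpec", contains = "NoiseSpec",
         representation(seed = "integer"))

#' A sampled corruption field
#'
#' Zero-mean, unit-variance (simplex fields exactly so by per-sample
#' standardization; Gaussian fields in distribution) noise used as
#' \eqn{\epsilon} in the diffusion equations.
#'
#' @slot values Numeric H x W matrix.
#' @slot spec The [NoiseSpec-class] that generated it, or `NULL` for fields
#'   that are network predictions rather than draws.
#' @exportClass NoiseField
setClass("NoiseField",
         representation(values = "matrix", spec = "ANY"))

setMethod("show", "NoiseField", function(object) {
  cat(sprintf("NoiseField %dx%d (%s): mean %.3g, var %.3g\n",
              nrow(object@values), ncol(object@values),
              if (is.null(object@spec)) "predicted" else class(object@spec)[1],
              mean(object@values), stats::var(as.vector(object@values))))
})

# ---- Denoiser ----------------------------------------------------------

#' Trainable noise-prediction network handle
#'
#' Opaque handle around the UNet-style noise predictor. Parameters, EMA
#' parameters, optimizer state, training step and the forward-evaluation
#' counter live in the `state` environment, giving the handle reference
#' semantics (the counter and training updates mutate in place).
#'
#' @slot config Named list describing the architecture (see
#'   [denoiserConfig()]).
#' @slot state Environment with `params`, `ema`, `opt`, `step`, `evalCount`,
#'   `lossLog`.
#' @exportClass Denoiser
setClass("Denoiser",
         representation(config = "list", state = "environment"))

setMethod("show", "Denoiser", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@state$params, length, numeric(1)))
  cat(sprintf(paste0("Denoiser: %dx%d input, base %d, levels %s, ",
                     "%d res block(s)/level, attention at {%s}\n",
                     "  %d parameters, trained %d step(s), %d evaluation(s)\n"),
              cfg$imageSize, cfg$imageSize, cfg$baseChannels,
              paste(cfg$channelMult, collapse = ","), cfg$numResBlocks,
              paste(cfg$attnResolutions, collapse = ","),
              as.integer(np), object@state$step, object@state$evalCount))
})

# ---- Anomaly map / binary mask -----------------------------------------

#' Per-pixel squared reconstruction error
#'
#' \eqn{E_{sq} = (x_0 - \hat{x}_0)^2} on unit-range images, plus a record of
#' how it was produced.
#'
#' @slot values Non-negative numeric matrix.
#' @slot lambda Sampling timestep used (NA if not applicable).
#' @slot sampler Character tag (`"single"`, `"iterative"`, `"direct"`).
#' @slot seed Seed used for the corruption draw (NA if none).
#' @exportClass AnomalyMap
setClass("AnomalyMap",
         representation(values = "matrix", lambda = "integer",
                        sampler = "character", seed = "integer"))

setValidity("AnomalyMap", function(object) {
  if (any(object@values < 0)) "values must be non-negative" else TRUE
})

setMethod("show", "AnomalyMap", function(object) {
  cat(sprintf("AnomalyMap %dx%d (%s, lambda = %s): max E_sq %.4f\n",
              nrow(object@values), ncol(object@values), object@sampler,
              ifelse(is.na(object@lambda), "NA", object@lambda),
              max(object@values)))
})

#' Binary segmentation mask with provenance
#'
#' @slot values Logical H x W matrix.
#' @slot provenance Named list (threshold `tau`, postprocessing settings,
#'   ensemble votes, ...).
#' @exportClass BinaryMask
setClass("BinaryMask",
         representation(values = "matrix", provenance = "list"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@values)) "values must be logical" else TRUE
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %dx%d: %d positive pixel(s)\n",
              nrow(object@values), ncol(object@values), sum(object@values)))
})

# ---- VolumeRecord ------------------------------------------------------

#' A loaded 3D volume with slice-range metadata
#'
#' @slot voxels Numeric 3D array.
#' @slot sliceAxis Integer axis index along which axial slices are taken.
#' @slot trainableRange Integer (lo, hi) slice indices considered usable.
#' @slot mask Optional 3D logical/numeric array of ground-truth anomalies
#'   (0-length array when absent).
#' @exportClass VolumeRecord
setClass("VolumeRecord",
         representation(voxels = "array", sliceAxis = "integer",
                        trainableRange = "integer", mask = "array"))

setValidity("VolumeRecord", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L) msgs <- c(msgs, "voxels must be 3D")
  if (length(object@mask) > 0 && !identical(dim(object@mask), dim(object@voxels)))
    msgs <- c(msgs, "mask shape must match voxels")
  rng <- object@trainableRange
  n <- dim(object@voxels)[object@sliceAxis]
  if (rng[1] < 1L || rng[2] > n || rng[1] > rng[2])
    msgs <- c(msgs, "trainableRange out of bounds")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "VolumeRecord", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VolumeRecord %s, axial axis %d (%d slice(s), trainable %d..%d)%s\n",
              paste(d, collapse = "x"), object@sliceAxis, d[object@sliceAxis],
              object@trainableRange[1], object@trainableRange[2],
              if (length(object@mask)) ", with ground-truth mask" else ""))
})

# ---- PhantomSpec -------------------------------------------------------

#' Synthetic-phantom population specification
#'
#' Parameters of the single-class "healthy" population (a soft-edged,
#' smoothly textured ellipse on a zero background) and of the injected
#' anomalies (soft disks of a configurable intensity offset).
#'
#' @slot size Image side length in pixels.
#' @slot nHealthy Default population size for [genHealthy()].
#' @slot anatomy Named list: `semiAxisA`, `semiAxisB` (ranges, px),
#'   `rotation` (range, rad), `centerJitter` (px), `baseIntensity`,
#'   `textureAmp`, `textureScale` (px), `edgeSoftness` (px).
#' @slot anomaly Named list: `radius` (range, px), `offset` (additive
#'   intensity), `count`, `edge` (rim softness, px).
#' @slot seed Integer master seed; all phantom randomness derives from it.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(size = "integer", nHealthy = "integer",
                        anatomy = "list", anomaly = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  an <- object@anatomy; am <- object@anomaly
  hi <- an$baseIntensity + an$textureAmp + max(0, am$offset)
  lo <- an$baseIntensity - an$textureAmp + min(0, am$offset)
  if (hi > 1 + 1e-9 || lo < -1e-9)
    msgs <- c(msgs, "anomaly offset must keep pixel values inside [0, 1]")
  if (any(am$radius < 0)) msgs <- c(msgs, "anomaly radius must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec %dx%d, %d healthy, anomaly r in [%g, %g] offset %+.2f\n",
              object@size, object@size, object@nHealthy,
              object@anomaly$radius[1], object@anomaly$radius[2],
              object@anomaly$offset))
})
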