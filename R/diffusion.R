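# Closed-form forward diffusion, the iterative DDPM reverse sampler, and the
# single-evaluation reconstruction that inverts the forward equation.

#' Forward-diffuse an image to timestep t in one closed-form step
#'
#' Computes \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,
#' \epsilon} directly, without walking the Markov chain.
#'
#' @param x0 Clean image, a symmetric-range [GrayImage-class].
#' @param eps Noise field (a [NoiseField-class] or matrix) of the same shape.
#' @param t Target timestep, 1..T.
#' @param sched A [ScheduleTable-class].
#' @return A [DiffusionSample-class] holding \eqn{x_t}, `t` and `eps`.
#' @examples
#' sched <- linearSchedule(1000)
#' x0 <- grayImage(matrix(0.2, 16, 16), "symmetric")
#' xs <- forwardDiffuse(x0, matrix(rnorm(256), 16), 300, sched)
#' @export
forwardDiffuse <- function(x0, eps, t, sched) {
  .checkT(sched, t)
  if (x0@range == "unit")
    stop("x0 must be on the symmetric [-1, 1] scale (see toSymmetric())",
         call. = FALSE)
  e <- .asPixelMatrix(eps)
  .assertSameShape(x0@pixels, e, "x0 and eps")
  ab <- sched@alphaBar[t]
  xt <- sqrt(ab) * x0@pixels + sqrt(1 - ab) * e
  new("DiffusionSample", xt = grayImage(xt, "free"), t = as.integer(t), eps = e)
}

#' Reconstruct the clean image from one noise prediction
#'
#' The algebraic inversion of the closed-form forward equation using the
#' predicted noise: \eqn{\hat{x}_0 = (x_t - \sqrt{1-\bar\alpha_t}\,
#' \hat\epsilon)/\sqrt{\bar\alpha_t}}. This is the single-step sampler: the
#' whole reverse process collapses into one denoiser evaluation, removing
#' all the noise estimated at timestep t and adding none back.
#'
#' @param xt Noised image ([GrayImage-class] or [DiffusionSample-class]).
#' @param epsHat Predicted noise (matrix or [NoiseField-class]).
#' @param t Timestep at which `xt` was produced.
#' @param sched A [ScheduleTable-class].
#' @param clip Clip the result into the symmetric range (default), the
#'   standard stabilizer before error-map computation. With `clip = FALSE`
#'   the raw inversion is returned (range tag `"free"`) for diagnostics.
#' @return A [GrayImage-class] estimate of \eqn{x_0}.
#' @export
singleStepDenoise <- function(xt, epsHat, t, sched, clip = TRUE) {
  .checkT(sched, t)
  if (is(xt, "DiffusionSample")) xt <- xt@xt
  e <- .asPixelMatrix(epsHat)
  .assertSameShape(xt@pixels, e, "xt and epsHat")
  ab <- sched@alphaBar[t]
  x0 <- (xt@pixels - sqrt(1 - ab) * e) / sqrt(ab)
  if (clip) grayImage(.clamp(x0, -1, 1), "symmetric") else grayImage(x0, "free")
}

#' One iterative reverse-diffusion step
#'
#' Samples \eqn{x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(x_t -
#' \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon\right) + \sigma_t z}
#' with the fixed variance choice \eqn{\sigma_t^2 = \beta_t}. At `t = 1`,
#' or when `z` is zero, the step is deterministic.
#'
#' @param xt Image at timestep t ([GrayImage-class]).
#' @param epsHat Predicted noise at t (matrix or [NoiseField-class]).
#' @param z Standardized noise for the stochastic term (matrix,
#'   [NoiseField-class], or `NULL` for a zero / deterministic step).
#' @param t Timestep, 1..T.
#' @param sched A [ScheduleTable-class].
#' @return A [GrayImage-class] (range `"free"`) at timestep t - 1.
#' @export
reverseStep <- function(xt, epsHat, z, t, sched) {
  .checkT(sched, t)
  if (is(xt, "DiffusionSample")) xt <- xt@xt
  e <- .asPixelMatrix(epsHat)
  .assertSameShape(xt@pixels, e, "xt and epsHat")
  mu <- (xt@pixels - sched@beta[t] / sqrt(1 - sched@alphaBar[t]) * e) /
    sqrt(sched@alpha[t])
  if (!is.null(z) && t > 1L) {
    zm <- .asPixelMatrix(z)
    .assertSameShape(xt@pixels, zm, "xt and z")
    mu <- mu + sqrt(sched@beta[t]) * zm
  }
  grayImage(mu, "free")
}

# Evaluate a denoiser handle or a plain function(x_matrix, t) -> matrix.
.evalDenoiser <- function(denoiser, x, t) {
  if (is(denoiser, "Denoiser")) return(pixels(predictNoise(denoiser, x, t)))
  if (is.function(denoiser)) return(denoiser(.asPixelMatrix(x), t))
  stop("denoiser must be a Denoiser or a function(x, t)", call. = FALSE)
}

#' Iterative DDPM reverse sampling from a partially noised image
#'
#' Applies [reverseStep()] for t = lambda, ..., 1, consuming exactly
#' `lambda` denoiser evaluations. With `deterministic = TRUE` the stochastic
#' term is dropped at every step; otherwise fresh standardized noise from
#' `noiseSpec` (Gaussian if `NULL`) is drawn per step.
#'
#' @param xLambda Image noised to timestep `lambda` ([GrayImage-class] or
#'   [DiffusionSample-class]).
#' @param lambda Starting timestep (0 returns the input unchanged).
#' @param denoiser A [Denoiser-class], or a function `(matrix, t) -> matrix`.
#' @param sched A [ScheduleTable-class].
#' @param deterministic Drop the \eqn{\sigma_t z} term everywhere.
#' @param noiseSpec Optional [NoiseSpec-class] for the stochastic term.
#' @param seed Optional seed for the stochastic draws.
#' @return A [GrayImage-class] (range `"free"`) estimate of \eqn{x_0}.
#' @export
iterativeSample <- function(xLambda, lambda, denoiser, sched,
                            deterministic = FALSE, noiseSpec = NULL,
                            seed = NULL) {
  lambda <- as.integer(lambda)
  if (lambda > sched@steps)
    stop("lambda exceeds the schedule length", call. = FALSE)
  if (is(xLambda, "DiffusionSample")) xLambda <- xLambda@xt
  if (lambda <= 0L) return(xLambda)
  withSeed(seed, {
    x <- xLambda
    h <- nrow(x@pixels); w <- ncol(x@pixels)
    for (t in seq(lambda, 1L)) {
      epsHat <- .evalDenoiser(denoiser, x, t)
      z <- if (deterministic || t == 1L) NULL else .reverseNoise(noiseSpec, h, w)
      x <- reverseStep(x, epsHat, z, t, sched)
    }
    x
  })
}

.reverseNoise <- function(noiseSpec, h, w) {
  if (is.null(noiseSpec)) return(matrix(rnorm(h * w), h, w))
  .sampleNoiseMatrix(.freshSpec(noiseSpec, .childSeed()), h, w)
}
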