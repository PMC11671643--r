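# DDPM training: sample an image, a uniform timestep and a fresh noise
# field; forward-diffuse; predict; L2 loss on the noise residual; AdamW
# update; EMA tracking of the parameters for inference.

#' Training configuration
#'
#' Defaults are the reference hyperparameters (AdamW, learning rate 1e-4,
#' betas 0.9/0.999, weight decay 0, EMA decay 0.9999, batch size 1,
#' T = 1000). Desk-scale runs use the `"mini"` profile (see
#' [readProfile()]), which shortens the run and speeds up the EMA so the
#' averaged parameters track a few-thousand-step training.
#'
#' @param iterations Number of optimizer steps.
#' @param batchSize Images per step; only the reference setting 1 is
#'   supported.
#' @param learningRate AdamW learning rate.
#' @param weightDecay Decoupled weight decay.
#' @param adamBetas Numeric length-2 vector of AdamW betas.
#' @param emaDecay EMA decay in `[0, 1]`.
#' @param timesteps Diffusion chain length T used for uniform t draws.
#' @param seed Master seed for the training stream.
#' @return Named list of validated settings.
#' @export
trainConfig <- function(iterations = 2000L, batchSize = 1L,
                        learningRate = 1e-4, weightDecay = 0,
                        adamBetas = c(0.9, 0.999), emaDecay = 0.9999,
                        timesteps = 1000L, seed = 1L) {
  if (learningRate <= 0) stop("learningRate must be > 0", call. = FALSE)
  if (emaDecay < 0 || emaDecay > 1) stop("emaDecay must be in [0, 1]", call. = FALSE)
  if (batchSize != 1L)
    stop("only batch size 1 (the reference setting) is implemented", call. = FALSE)
  list(iterations = as.integer(iterations), batchSize = 1L,
       learningRate = learningRate, weightDecay = weightDecay,
       adamBetas = adamBetas, emaDecay = emaDecay,
       timesteps = as.integer(timesteps), seed = as.integer(seed))
}

#' Exponential-moving-average update of a parameter set
#'
#' `ema <- decay * ema + (1 - decay) * params`, elementwise, recursing
#' through nested parameter lists.
#'
#' @param emaParams Current EMA parameters (array or nested list).
#' @param params Raw parameters of matching structure.
#' @param decay Decay rate in `[0, 1]` (1 leaves the EMA unchanged, 0
#'   copies the raw parameters).
#' @return Updated EMA parameters.
#' @examples
#' emaUpdate(0, 1, 0.9)  # 0.1
#' @export
emaUpdate <- function(emaParams, params, decay) {
  if (is.list(emaParams)) {
    if (!is.list(params) || length(params) != length(emaParams))
      stop("parameter structures do not match", call. = FALSE)
    return(mapply(emaUpdate, emaParams, params,
                  MoreArgs = list(decay = decay), SIMPLIFY = FALSE))
  }
  if (!identical(dim(emaParams), dim(params)) ||
      length(emaParams) != length(params))
    stop("parameter shapes do not match", call. = FALSE)
  decay * emaParams + (1 - decay) * params
}

.adamUpdate <- function(st, grads, lr, betas, wd, eps = 1e-8) {
  if (is.null(st$opt))
    st$opt <- list(m = .zeroLike(st$params), v = .zeroLike(st$params), t = 0L)
  opt <- st$opt
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  P <- st$params
  for (ln in names(P)) for (pn in names(P[[ln]])) {
    g <- grads[[ln]][[pn]]
    m <- b1 * opt$m[[ln]][[pn]] + (1 - b1) * g
    v <- b2 * opt$v[[ln]][[pn]] + (1 - b2) * g * g
    opt$m[[ln]][[pn]] <- m
    opt$v[[ln]][[pn]] <- v
    P[[ln]][[pn]] <- P[[ln]][[pn]] -
      lr * ((m / c1) / (sqrt(v / c2) + eps) + wd * P[[ln]][[pn]])
  }
  st$params <- P
  st$opt <- opt
  invisible(NULL)
}

.asSymmetricMatrix <- function(x0) {
  if (is(x0, "GrayImage")) {
    if (x0@range == "unit") x0 <- toSymmetric(x0)
    if (x0@range != "symmetric")
      stop("training images must be unit- or symmetric-range", call. = FALSE)
    return(x0@pixels)
  }
  .asPixelMatrix(x0)
}

#' One training step
#'
#' Draws `t ~ Uniform{1..T}` and a fresh noise field, forward-diffuses the
#' image, evaluates the network, computes the L2 loss
#' `mean((eps - epsHat)^2)`, backpropagates, applies one AdamW update and
#' advances the EMA. All randomness is taken from the caller's RNG stream.
#'
#' With a `predictor` function supplied the step runs in diagnostic mode:
#' the loss is computed against that predictor and no update is applied.
#'
#' @param h A [Denoiser-class].
#' @param x0 Clean image ([GrayImage-class] or matrix) in symmetric range
#'   (unit-range GrayImages are converted).
#' @param sched A [ScheduleTable-class].
#' @param noiseSpec A [NoiseSpec-class]; a fresh field is drawn per step.
#' @param learningRate,adamBetas,weightDecay,emaDecay Optimizer settings
#'   (see [trainConfig()]).
#' @param predictor Optional function `(matrix, t) -> matrix` for diagnostic
#'   loss evaluation.
#' @return The scalar loss, invisibly.
#' @export
trainingStep <- function(h, x0, sched, noiseSpec = simplexSpec(),
                         learningRate = 1e-4, adamBetas = c(0.9, 0.999),
                         weightDecay = 0, emaDecay = 0.9999,
                         predictor = NULL) {
  x0m <- .asSymmetricMatrix(x0)
  t <- sample.int(sched@steps, 1L)
  eps <- .sampleNoiseMatrix(.freshSpec(noiseSpec, .childSeed()),
                            nrow(x0m), ncol(x0m))
  ab <- sched@alphaBar[t]
  xt <- sqrt(ab) * x0m + sqrt(1 - ab) * eps

  if (!is.null(predictor)) {
    loss <- mean((eps - predictor(xt, t))^2)
    return(invisible(loss))
  }

  st <- h@state
  G <- new.env(parent = emptyenv())
  G$g <- .zeroLike(st$params)
  fw <- .unetApply(st$params, h@config, xt, t, G)
  st$evalCount <- st$evalCount + 1L
  resid <- fw$out - eps
  loss <- mean(resid^2)
  if (!is.finite(loss))
    stop(sprintf("non-finite training loss at step %d (t = %d): %s",
                 st$step + 1L, t, format(loss)), call. = FALSE)
  fw$bw(2 * resid / length(resid))
  .adamUpdate(st, G$g, learningRate, adamBetas, weightDecay)
  # flat-loop EMA (same arithmetic as emaUpdate, without recursion overhead)
  ema <- st$ema; P <- st$params
  for (ln in names(P)) for (pn in names(P[[ln]]))
    ema[[ln]][[pn]] <- emaDecay * ema[[ln]][[pn]] + (1 - emaDecay) * P[[ln]][[pn]]
  st$ema <- ema
  st$step <- st$step + 1L
  st$lossLog <- c(st$lossLog, loss)
  invisible(loss)
}

#' Train a denoiser on a healthy image population
#'
#' Seeded, resumable training loop. Each iteration samples one image
#' uniformly from `images` and performs one [trainingStep()]. Inference
#' ([predictNoise()]) uses the EMA parameters by default.
#'
#' @param images List of [GrayImage-class] objects (or matrices) -- the
#'   healthy population; or a 3D array with images along the third axis.
#' @param denoiser A [Denoiser-class] to continue training, or `NULL` to
#'   build one from `config`.
#' @param config Architecture from [denoiserConfig()] (ignored when
#'   `denoiser` is given).
#' @param train Settings from [trainConfig()].
#' @param sched A [ScheduleTable-class]; defaults to the linear schedule of
#'   length `train$timesteps`.
#' @param noiseSpec Corruption model, default multi-octave simplex noise.
#' @param checkpointPath,checkpointEvery Write a checkpoint to
#'   `checkpointPath` every `checkpointEvery` steps (0 disables).
#' @param logFile Optional CSV path for the (step, loss) curve.
#' @param verbose Print a running-mean loss every 100 steps.
#' @return The trained [Denoiser-class].
#' @export
trainDenoiser <- function(images, denoiser = NULL, config = NULL,
                          train = trainConfig(), sched = NULL,
                          noiseSpec = simplexSpec(),
                          checkpointPath = NULL, checkpointEvery = 0L,
                          logFile = NULL, verbose = FALSE) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(i) images[, , i])
  if (length(images) == 0L) stop("empty training dataset", call. = FALSE)
  if (is.null(denoiser)) {
    if (is.null(config)) stop("either a denoiser or a config is required", call. = FALSE)
    denoiser <- buildDenoiser(config, seed = train$seed)
  }
  if (is.null(sched)) sched <- linearSchedule(train$timesteps)
  mats <- lapply(images, .asSymmetricMatrix)

  # Seed offset by the current step so a resumed run continues on a fresh,
  # reproducible stream.
  withSeed(train$seed + denoiser@state$step, {
    for (it in seq_len(train$iterations)) {
      x0 <- mats[[sample.int(length(mats), 1L)]]
      loss <- trainingStep(denoiser, x0, sched, noiseSpec,
                           learningRate = train$learningRate,
                           adamBetas = train$adamBetas,
                           weightDecay = train$weightDecay,
                           emaDecay = train$emaDecay)
      if (verbose && it %% 100L == 0L) {
        recent <- utils::tail(denoiser@state$lossLog, 100L)
        message(sprintf("step %d: loss %.4f (mean of last %d: %.4f)",
                        denoiser@state$step, loss, length(recent), mean(recent)))
      }
      if (checkpointEvery > 0L && !is.null(checkpointPath) &&
          denoiser@state$step %% checkpointEvery == 0L)
        saveCheckpoint(denoiser, checkpointPath)
    }
  })
  if (!is.null(checkpointPath)) saveCheckpoint(denoiser, checkpointPath)
  if (!is.null(logFile))
    utils::write.csv(trainingLog(denoiser), logFile, row.names = FALSE)
  denoiser
}
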