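# The anomaly-detection pipeline: partial noising, reconstruction
# (single-evaluation or iterative), squared-error map, thresholding,
# morphological postprocessing, and the multi-timestep voting ensemble.

#' Per-pixel squared reconstruction error
#'
#' \eqn{E_{sq} = (x_0 - \hat{x}_0)^2} between two unit-range images. High
#' values mark pixels the healthy-trained model could not reproduce -- the
#' anomaly signal.
#'
#' @param x0 Original image, unit range.
#' @param x0Hat Reconstruction, unit range.
#' @param lambda,sampler,seed Optional provenance.
#' @return An [AnomalyMap-class].
#' @export
anomalyMap <- function(x0, x0Hat, lambda = NA_integer_, sampler = "direct",
                       seed = NA_integer_) {
  for (im in list(x0, x0Hat))
    if (is(im, "GrayImage") && im@range != "unit")
      stop("anomaly maps are computed on unit-range images", call. = FALSE)
  a <- .asPixelMatrix(x0); b <- .asPixelMatrix(x0Hat)
  .assertSameShape(a, b, "x0 and x0Hat")
  new("AnomalyMap", values = (a - b)^2, lambda = as.integer(lambda),
      sampler = sampler, seed = as.integer(seed))
}

#' Threshold an anomaly map into a binary mask
#'
#' A pixel is anomalous iff `E_sq > tau`. The default tau = 0.3 lives on
#' the squared-error scale of unit-range images, i.e. it corresponds to an
#' absolute intensity difference of about 0.55.
#'
#' @param m An [AnomalyMap-class] (or matrix).
#' @param tau Threshold, >= 0.
#' @return A [BinaryMask-class].
#' @export
thresholdMask <- function(m, tau = 0.3) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  v <- .asPixelMatrix(m)
  new("BinaryMask", values = v > tau, provenance = list(tau = tau))
}

# 8-connected component labelling (two-pass flood fill via queue).
.label8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(m)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- (q - 1L) %% H + 1L
      j <- (q - 1L) %/% H + 1L
      for (dj in -1:1) {
        nj <- j + dj
        if (nj < 1L || nj > W) next
        base <- (nj - 1L) * H
        for (di in -1:1) {
          ni <- i + di
          if (ni < 1L || ni > H) next
          np <- base + ni
          if (m[np] && lab[np] == 0L) {
            lab[np] <- cur
            queue <- c(queue, np)
          }
        }
      }
    }
  }
  lab
}

#' Postprocessing configuration for predicted masks
#' @param kernel Dilation structuring-element side (odd, >= 1; 1 disables).
#' @param keepK Number of largest connected components to retain.
#' @param minArea Minimum component area (pixels, measured after dilation).
#' @return Named list.
#' @export
postConfig <- function(kernel = 3L, keepK = 1L, minArea = 5L) {
  if (kernel %% 2 != 1 || kernel < 1) stop("kernel must be odd and >= 1", call. = FALSE)
  list(kernel = as.integer(kernel), keepK = as.integer(keepK),
       minArea = as.integer(minArea))
}

#' Postprocess a binary mask
#'
#' Binary dilation with a `kernel` x `kernel` box, then retention of only
#' the `keepK` largest 8-connected components with area at least `minArea`.
#' Removes the scattered false-positive specks that squared-error
#' thresholding produces while keeping the dominant anomalous region(s).
#'
#' @param mask A [BinaryMask-class] (or logical matrix).
#' @param kernel,keepK,minArea See [postConfig()].
#' @return A [BinaryMask-class].
#' @export
postprocessMask <- function(mask, kernel = 3L, keepK = 1L, minArea = 5L) {
  v <- if (is(mask, "BinaryMask")) mask@values else mask
  prov <- if (is(mask, "BinaryMask")) mask@provenance else list()
  if (any(v)) {
    if (kernel > 1L) {
      d <- EBImage::dilate(v * 1, EBImage::makeBrush(kernel, shape = "box"))
      v <- d > 0.5
    }
    lab <- .label8(v)
    if (max(lab) > 0L) {
      areas <- tabulate(lab[lab > 0L])
      keep <- order(areas, decreasing = TRUE)
      keep <- keep[seq_len(min(keepK, length(keep)))]
      keep <- keep[areas[keep] >= minArea]
      v <- matrix(lab %in% keep, nrow(v), ncol(v)) & v
    }
  }
  prov$post <- list(kernel = kernel, keepK = keepK, minArea = minArea)
  new("BinaryMask", values = v, provenance = prov)
}

# Shared core: partial noising + reconstruction + raw (pre-postprocessing)
# thresholded mask. Consumes exactly 1 (single) or lambda (iterative)
# denoiser evaluations.
.segmentCore <- function(x0, lambda, denoiser, sched, noiseSpec, tau,
                         sampler, seed, deterministic = FALSE) {
  if (is(x0, "GrayImage") && x0@range != "unit")
    stop("segmentation expects a unit-range input image", call. = FALSE)
  x0u <- if (is(x0, "GrayImage")) x0 else grayImage(.asPixelMatrix(x0), "unit")
  withSeed(seed, {
    x0s <- toSymmetric(x0u)
    h <- nrow(x0s@pixels); w <- ncol(x0s@pixels)
    eps <- .sampleNoiseMatrix(.freshSpec(noiseSpec, .childSeed()), h, w)
    xs <- forwardDiffuse(x0s, eps, lambda, sched)
    recon <-
      if (sampler == "single") {
        epsHat <- .evalDenoiser(denoiser, xs@xt, lambda)
        singleStepDenoise(xs, epsHat, lambda, sched, clip = TRUE)
      } else {
        raw <- iterativeSample(xs, lambda, denoiser, sched,
                               deterministic = deterministic,
                               noiseSpec = noiseSpec)
        clipImage(raw, "symmetric")
      }
    reconU <- toUnit(recon)
    m <- anomalyMap(x0u, reconU, lambda = lambda, sampler = sampler,
                    seed = seed %||% NA_integer_)
    list(map = m, rawMask = thresholdMask(m, tau), recon = reconU)
  })
}

.checkLambdaWindow <- function(lambda, window) {
  if (lambda < window[1] || lambda > window[2])
    warning(sprintf("lambda = %d lies outside the recommended window [%d, %d]",
                    lambda, window[1], window[2]), call. = FALSE)
}

#' Single-evaluation anomaly segmentation
#'
#' The fast path: partially noise the input to timestep `lambda`, predict
#' the noise once, invert the forward equation to a reconstruction, and
#' threshold + postprocess the squared-error map. Exactly one denoiser
#' evaluation regardless of `lambda` -- O(1) sampling cost versus the
#' O(lambda) iterative sampler.
#'
#' @param x0 Input image, unit range.
#' @param lambda Partial-diffusion timestep; the window that preserves
#'   enough structure to reconstruct from is about 250-400 (default 300).
#'   With `randomLambda = TRUE` a seeded uniform draw from `lambdaWindow`
#'   is used instead.
#' @param denoiser A trained [Denoiser-class] (or predictor function).
#' @param sched A [ScheduleTable-class].
#' @param noiseSpec Corruption model (default simplex octaves).
#' @param tau Error-map threshold (see [thresholdMask()]).
#' @param post Postprocessing settings from [postConfig()]; `NULL` skips
#'   postprocessing.
#' @param seed Seed for the corruption draw.
#' @param randomLambda Draw lambda uniformly from `lambdaWindow`.
#' @param lambdaWindow Recommended (and warned-about) lambda range.
#' @return List with `mask` ([BinaryMask-class]), `map`
#'   ([AnomalyMap-class]) and `recon` ([GrayImage-class], unit range).
#' @export
segmentSingle <- function(x0, lambda = 300L, denoiser, sched,
                          noiseSpec = simplexSpec(), tau = 0.3,
                          post = postConfig(), seed = NULL,
                          randomLambda = FALSE,
                          lambdaWindow = c(250L, 400L)) {
  if (randomLambda)
    lambda <- withSeed(seed, sample(seq(lambdaWindow[1], lambdaWindow[2]), 1L))
  lambda <- as.integer(lambda)
  .checkLambdaWindow(lambda, lambdaWindow)
  core <- .segmentCore(x0, lambda, denoiser, sched, noiseSpec, tau,
                       "single", seed)
  mask <- if (is.null(post)) core$rawMask
          else postprocessMask(core$rawMask, post$kernel, post$keepK, post$minArea)
  list(mask = mask, map = core$map, recon = core$recon)
}

#' Iterative (classical DDPM) anomaly segmentation
#'
#' As [segmentSingle()], but the reconstruction walks the learned reverse
#' chain from `lambda` down to 0, consuming exactly `lambda` denoiser
#' evaluations.
#'
#' @inheritParams segmentSingle
#' @param deterministic Drop the stochastic term of every reverse step.
#' @return List with `mask`, `map`, `recon`.
#' @export
segmentIterative <- function(x0, lambda = 300L, denoiser, sched,
                             noiseSpec = simplexSpec(), tau = 0.3,
                             post = postConfig(), seed = NULL,
                             deterministic = FALSE,
                             lambdaWindow = c(250L, 400L)) {
  lambda <- as.integer(lambda)
  .checkLambdaWindow(lambda, lambdaWindow)
  core <- .segmentCore(x0, lambda, denoiser, sched, noiseSpec, tau,
                       "iterative", seed, deterministic = deterministic)
  mask <- if (is.null(post)) core$rawMask
          else postprocessMask(core$rawMask, post$kernel, post$keepK, post$minArea)
  list(mask = mask, map = core$map, recon = core$recon)
}

#' Multi-timestep ensemble segmentation
#'
#' Runs the single-evaluation segmenter once per timestep in `lambdas`
#' (fresh corruption each), counts per-pixel votes over the raw
#' (pre-postprocessing) masks, keeps pixels detected at least `minVotes`
#' times, and postprocesses the vote mask once. Averaging over timesteps
#' stabilizes the stochastic per-run masks.
#'
#' @inheritParams segmentSingle
#' @param lambdas Integer vector of partial-diffusion timesteps (default
#'   250, 300, 350, 400).
#' @param minVotes Minimum detections for a pixel to survive; defaults to a
#'   majority, `ceiling(length(lambdas) / 2)`.
#' @return A [BinaryMask-class] (vote counts in `provenance$votes`).
#' @export
ensembleSegment <- function(x0, lambdas = c(250L, 300L, 350L, 400L),
                            denoiser, sched, noiseSpec = simplexSpec(),
                            tau = 0.3, minVotes = NULL,
                            post = postConfig(), seed = NULL) {
  if (length(lambdas) == 0L) stop("lambdas must be non-empty", call. = FALSE)
  if (is.null(minVotes)) minVotes <- ceiling(length(lambdas) / 2)
  if (minVotes > length(lambdas))
    stop("minVotes cannot exceed the number of timesteps", call. = FALSE)
  votes <- NULL
  withSeed(seed, {
    for (lam in as.integer(lambdas)) {
      core <- .segmentCore(x0, lam, denoiser, sched, noiseSpec, tau,
                           "single", seed = .childSeed())
      v <- core$rawMask@values
      votes <- if (is.null(votes)) v * 1L else votes + v
    }
  })
  kept <- new("BinaryMask", values = votes >= minVotes,
              provenance = list(tau = tau, minVotes = minVotes,
                                lambdas = as.integer(lambdas), votes = votes))
  out <- if (is.null(post)) kept
         else postprocessMask(kept, post$kernel, post$keepK, post$minArea)
  out@provenance$votes <- votes
  out@provenance$minVotes <- minVotes
  out
}

#' Tune the error-map threshold on a validation split
#'
#' Grid-searches tau to maximize mean IoU of the postprocessed masks
#' against ground truth. The raw squared-error scale depends on how well
#' the trained model reconstructs healthy tissue, so a small labelled
#' validation split is the practical way to place tau.
#'
#' @param maps List of [AnomalyMap-class] objects.
#' @param truths List of matching ground-truth [BinaryMask-class] objects
#'   (or logical matrices).
#' @param taus Candidate thresholds.
#' @param post Postprocessing applied to each candidate mask (as in the
#'   final pipeline); `NULL` to tune on raw masks.
#' @return The tau with the highest mean IoU.
#' @export
tuneThreshold <- function(maps, truths, taus = seq(0.01, 0.5, by = 0.01),
                          post = postConfig()) {
  stopifnot(length(maps) == length(truths), length(maps) > 0)
  mi <- vapply(taus, function(tau) {
    ious <- mapply(function(m, tr) {
      mk <- thresholdMask(m, tau)
      if (!is.null(post))
        mk <- postprocessMask(mk, post$kernel, post$keepK, post$minArea)
      segScores(mk, tr)$iou
    }, maps, truths)
    mean(ious)
  }, numeric(1))
  taus[which.max(mi)]
}
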