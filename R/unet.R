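# UNet-style noise predictor with analytic gradients.
#
# The network follows the standard DDPM backbone: a 3x3 stem convolution, an
# encoder of residual blocks (group norm -> SiLU -> conv, with the timestep
# embedding projected into every block) with optional self-attention at
# configured spatial resolutions and stride-2 convolutional downsampling; a
# bottleneck of residual block / attention / residual block; and a mirrored
# decoder with pass-through skip connections concatenated at equal
# resolutions, nearest-neighbour upsampling and a zero-initialized output
# convolution. Gradients are exact: every forward primitive returns a
# backward closure, and the network-level backward walks the recorded tape
# in reverse, routing skip-connection and timestep-embedding gradients
# explicitly.

#' Denoiser architecture configuration
#'
#' @param imageSize Input side length; must be divisible by
#'   `2^(length(channelMult) - 1)`.
#' @param baseChannels Channels at the highest resolution.
#' @param channelMult Per-level channel multipliers; its length sets the
#'   number of resolution levels.
#' @param numResBlocks Residual blocks per level.
#' @param attnResolutions Spatial resolutions (level side lengths) at which
#'   self-attention is inserted; must be a subset of the level resolutions.
#'   The bottleneck always carries one attention block.
#' @param numHeads Attention heads (must divide the channel count at every
#'   attention site).
#' @param dropout Dropout rate; only 0 is supported (the reference setting).
#' @param inChannels Input channels (1 for grayscale).
#' @return Named list with validated fields plus `tembDim`.
#' @examples
#' cfg <- denoiserConfig(64, baseChannels = 16, channelMult = c(1, 2))
#' @export
denoiserConfig <- function(imageSize, baseChannels = 128L,
                           channelMult = c(1L, 1L, 2L, 3L, 4L),
                           numResBlocks = 2L,
                           attnResolutions = c(32L, 16L),
                           numHeads = 1L, dropout = 0, inChannels = 1L) {
  L <- length(channelMult)
  if (imageSize %% 2^(L - 1) != 0)
    stop("imageSize must be divisible by 2^(levels - 1)", call. = FALSE)
  resL <- imageSize %/% 2^(0:(L - 1))
  if (length(attnResolutions) && !all(attnResolutions %in% resL))
    stop("attnResolutions must be a subset of the level resolutions (",
         paste(resL, collapse = ", "), ")", call. = FALSE)
  if (dropout != 0)
    stop("only dropout = 0 is supported", call. = FALSE)
  chs <- as.integer(baseChannels * channelMult)
  attnCh <- chs[match(c(attnResolutions, resL[L]), resL)]
  if (any(attnCh %% numHeads != 0))
    stop("numHeads must divide the channel count at every attention site",
         call. = FALSE)
  list(imageSize = as.integer(imageSize),
       baseChannels = as.integer(baseChannels),
       channelMult = as.integer(channelMult),
       numResBlocks = as.integer(numResBlocks),
       attnResolutions = as.integer(attnResolutions),
       numHeads = as.integer(numHeads),
       dropout = dropout,
       inChannels = as.integer(inChannels),
       tembDim = 4L * as.integer(baseChannels))
}

#' Sinusoidal timestep embedding
#'
#' Standard transformer positional encoding of an integer timestep:
#' `dim/2` sine and `dim/2` cosine components at geometrically spaced
#' frequencies from 1 down to ~1/10000.
#'
#' @param t Non-negative integer timestep.
#' @param dim Embedding dimension (even).
#' @return Numeric vector of length `dim`.
#' @examples
#' timeEmbedding(0, 8)  # sines all 0, cosines all 1
#' @export
timeEmbedding <- function(t, dim) {
  if (dim %% 2 != 0) stop("embedding dimension must be even", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / half)
  c(sin(t * freqs), cos(t * freqs))
}

# ---- parameter initialization ------------------------------------------

.ngroups <- function(C) {
  for (g in seq(min(8L, C), 1L)) if (C %% g == 0L) return(g)
  1L
}

.convInit <- function(k, cin, cout, zero = FALSE) {
  fanin <- k * k * cin
  W <- if (zero) matrix(0, fanin, cout)
       else matrix(rnorm(fanin * cout, sd = sqrt(2 / fanin)), fanin, cout)
  list(W = W, b = numeric(cout))
}

.denseInit <- function(din, dout, zero = FALSE) {
  W <- if (zero) matrix(0, din, dout)
       else matrix(rnorm(din * dout, sd = 1 / sqrt(din)), din, dout)
  list(W = W, b = numeric(dout))
}

.gnInit <- function(C) list(gamma = rep(1, C), beta = numeric(C))

.resBlockInit <- function(P, name, cin, cout, tdim) {
  P[[paste0(name, "_gn1")]] <- .gnInit(cin)
  P[[paste0(name, "_conv1")]] <- .convInit(3L, cin, cout)
  P[[paste0(name, "_temb")]] <- .denseInit(tdim, cout)
  P[[paste0(name, "_gn2")]] <- .gnInit(cout)
  # zero-initialized: every residual block starts as an identity map
  P[[paste0(name, "_conv2")]] <- .convInit(3L, cout, cout, zero = TRUE)
  if (cin != cout) P[[paste0(name, "_skip")]] <- .convInit(1L, cin, cout)
  P
}

.attnInit <- function(P, name, C) {
  P[[paste0(name, "_gn")]] <- .gnInit(C)
  P[[paste0(name, "_qkv")]] <- .denseInit(C, 3L * C)
  P[[paste0(name, "_proj")]] <- .denseInit(C, C, zero = TRUE)
  P
}

.initParams <- function(cfg, seed) {
  withSeed(seed, {
    L <- length(cfg$channelMult)
    chs <- cfg$baseChannels * cfg$channelMult
    resL <- cfg$imageSize %/% 2^(0:(L - 1))
    P <- list()
    P$temb_d1 <- .denseInit(cfg$baseChannels, cfg$tembDim)
    P$temb_d2 <- .denseInit(cfg$tembDim, cfg$tembDim)
    P$conv_in <- .convInit(3L, cfg$inChannels, chs[1])
    cin <- chs[1]
    for (i in seq_len(L)) {
      for (j in seq_len(cfg$numResBlocks)) {
        P <- .resBlockInit(P, sprintf("down%d_res%d", i, j), cin, chs[i], cfg$tembDim)
        cin <- chs[i]
        if (resL[i] %in% cfg$attnResolutions)
          P <- .attnInit(P, sprintf("down%d_attn%d", i, j), chs[i])
      }
      if (i < L) P[[sprintf("down%d_ds", i)]] <- .convInit(3L, chs[i], chs[i])
    }
    P <- .resBlockInit(P, "mid_res1", chs[L], chs[L], cfg$tembDim)
    P <- .attnInit(P, "mid_attn", chs[L])
    P <- .resBlockInit(P, "mid_res2", chs[L], chs[L], cfg$tembDim)
    cur <- chs[L]
    for (i in seq(L, 1L)) {
      for (j in seq_len(cfg$numResBlocks)) {
        cinUp <- if (j == 1L) cur + chs[i] else chs[i]
        P <- .resBlockInit(P, sprintf("up%d_res%d", i, j), cinUp, chs[i], cfg$tembDim)
        if (resL[i] %in% cfg$attnResolutions)
          P <- .attnInit(P, sprintf("up%d_attn%d", i, j), chs[i])
      }
      cur <- chs[i]
      if (i > 1L) P[[sprintf("up%d_us", i)]] <- .convInit(3L, chs[i], chs[i])
    }
    P$out_gn <- .gnInit(chs[1])
    P$out_conv <- .convInit(3L, chs[1], cfg$inChannels, zero = TRUE)
    P
  })
}

.zeroLike <- function(P) {
  lapply(P, function(layer) lapply(layer, function(a) {
    z <- a; z[] <- 0; z
  }))
}

.accum <- function(G, pname, slot, val) {
  G$g[[pname]][[slot]] <- G$g[[pname]][[slot]] + val
  invisible(NULL)
}

# ---- differentiable primitives -----------------------------------------
# Each returns list(y, bw); bw maps the output gradient to the input
# gradient and accumulates parameter gradients into G$g. With G = NULL the
# backward closure is omitted (inference path).

.convF <- function(x, pname, P, G, k = 3L, stride = 1L, pad = 1L) {
  p <- P[[pname]]
  if (is.null(G)) return(list(y = conv2d_fwd(x, p$W, p$b, k, stride, pad),
                              bw = NULL))
  f <- conv2d_fwd_train(x, p$W, p$b, k, stride, pad)
  bw <- function(dy) {
    r <- conv2d_bwd_cached(f$col, dim(x), p$W, dy, k, stride, pad)
    .accum(G, pname, "W", r$dW)
    .accum(G, pname, "b", as.numeric(r$db))
    r$dx
  }
  list(y = f$y, bw = bw)
}

.denseF <- function(v, pname, P, G) {
  p <- P[[pname]]
  y <- as.vector(v %*% p$W) + p$b
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) {
    .accum(G, pname, "W", outer(v, dy))
    .accum(G, pname, "b", dy)
    as.vector(p$W %*% dy)
  }
  list(y = y, bw = bw)
}

.siluF <- function(x, G) {
  y <- silu_fwd(x)
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) silu_bwd(x, dy)
  list(y = y, bw = bw)
}

.gnF <- function(x, pname, P, G) {
  p <- P[[pname]]
  g <- .ngroups(dim(x)[3])
  f <- gn_fwd(x, p$gamma, p$beta, g)
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) {
    r <- gn_bwd(dy, f$xhat, f$invstd, p$gamma, g)
    .accum(G, pname, "gamma", as.numeric(r$dgamma))
    .accum(G, pname, "beta", as.numeric(r$dbeta))
    r$dx
  }
  list(y = f$y, bw = bw)
}

.up2F <- function(x, G) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) {
    a <- dy[seq(1, 2 * d[1], 2), , , drop = FALSE] +
      dy[seq(2, 2 * d[1], 2), , , drop = FALSE]
    a[, seq(1, 2 * d[2], 2), , drop = FALSE] +
      a[, seq(2, 2 * d[2], 2), , drop = FALSE]
  }
  list(y = y, bw = bw)
}

.resBlockF <- function(x, tact, name, P, G) {
  g1 <- .gnF(x, paste0(name, "_gn1"), P, G)
  s1 <- .siluF(g1$y, G)
  c1 <- .convF(s1$y, paste0(name, "_conv1"), P, G)
  tp <- .denseF(tact, paste0(name, "_temb"), P, G)
  d <- dim(c1$y); HW <- d[1] * d[2]
  h <- c1$y + rep(tp$y, each = HW)
  g2 <- .gnF(h, paste0(name, "_gn2"), P, G)
  s2 <- .siluF(g2$y, G)
  c2 <- .convF(s2$y, paste0(name, "_conv2"), P, G)
  hasSkip <- !is.null(P[[paste0(name, "_skip")]])
  sk <- if (hasSkip) .convF(x, paste0(name, "_skip"), P, G, k = 1L, pad = 0L)
        else NULL
  y <- (if (hasSkip) sk$y else x) + c2$y
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) {
    dh <- g2$bw(s2$bw(c2$bw(dy)))
    dtact <- tp$bw(colSums(matrix(dh, HW, d[3])))
    dx <- g1$bw(s1$bw(c1$bw(dh)))
    dx <- dx + (if (hasSkip) sk$bw(dy) else dy)
    list(dx = dx, dtact = dtact)
  }
  list(y = y, bw = bw)
}

.attnF <- function(x, name, P, G, heads) {
  dims <- dim(x); HW <- dims[1] * dims[2]; C <- dims[3]
  dh <- C %/% heads
  scale <- 1 / sqrt(dh)
  gn <- .gnF(x, paste0(name, "_gn"), P, G)
  X <- matrix(gn$y, HW, C)
  pq <- P[[paste0(name, "_qkv")]]
  QKV <- X %*% pq$W + rep(pq$b, each = HW)
  O <- matrix(0, HW, C)
  As <- vector("list", heads)
  for (hh in seq_len(heads)) {
    idx <- ((hh - 1) * dh + 1):(hh * dh)
    S <- tcrossprod(QKV[, idx, drop = FALSE], QKV[, C + idx, drop = FALSE]) * scale
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    As[[hh]] <- A
    O[, idx] <- A %*% QKV[, 2 * C + idx, drop = FALSE]
  }
  pp <- P[[paste0(name, "_proj")]]
  out <- O %*% pp$W + rep(pp$b, each = HW)
  y <- x + array(out, dims)
  bw <- NULL
  if (!is.null(G)) bw <- function(dy) {
    dout <- matrix(dy, HW, C)
    .accum(G, paste0(name, "_proj"), "W", crossprod(O, dout))
    .accum(G, paste0(name, "_proj"), "b", colSums(dout))
    dO <- tcrossprod(dout, pp$W)
    dQKV <- matrix(0, HW, 3L * C)
    for (hh in seq_len(heads)) {
      idx <- ((hh - 1) * dh + 1):(hh * dh)
      A <- As[[hh]]
      Q <- QKV[, idx, drop = FALSE]
      K <- QKV[, C + idx, drop = FALSE]
      V <- QKV[, 2 * C + idx, drop = FALSE]
      dOh <- dO[, idx, drop = FALSE]
      dA <- tcrossprod(dOh, V)
      dS <- A * (dA - rowSums(dA * A)) * scale
      dQKV[, idx] <- dS %*% K
      dQKV[, C + idx] <- crossprod(dS, Q)
      dQKV[, 2 * C + idx] <- crossprod(A, dOh)
    }
    .accum(G, paste0(name, "_qkv"), "W", crossprod(X, dQKV))
    .accum(G, paste0(name, "_qkv"), "b", colSums(dQKV))
    dX <- tcrossprod(dQKV, pq$W)
    dy + gn$bw(array(dX, dims))
  }
  list(y = y, bw = bw)
}

# ---- whole-network forward / backward ----------------------------------

# Returns list(out = H x W matrix, bw = function(dout) -> input gradient).
# When G is NULL only the forward pass is built.
.unetApply <- function(P, cfg, x, t, G = NULL) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (dim(x)[1] != cfg$imageSize || dim(x)[2] != cfg$imageSize)
    stop(sprintf("input is %dx%d but the denoiser expects %dx%d",
                 dim(x)[1], dim(x)[2], cfg$imageSize, cfg$imageSize),
         call. = FALSE)
  L <- length(cfg$channelMult)
  resL <- cfg$imageSize %/% 2^(0:(L - 1))
  nres <- cfg$numResBlocks
  train <- !is.null(G)

  te0 <- timeEmbedding(t, cfg$baseChannels)
  d1 <- .denseF(te0, "temb_d1", P, G)
  s1 <- .siluF(d1$y, G)
  d2 <- .denseF(s1$y, "temb_d2", P, G)
  sa <- .siluF(d2$y, G)
  tact <- sa$y

  ops <- vector("list", 0L)
  push <- function(o) ops[[length(ops) + 1L]] <<- o

  cin <- .convF(x, "conv_in", P, G)
  h <- cin$y
  push(list(kind = "lin", bw = cin$bw))

  skipStack <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(nres)) {
      rb <- .resBlockF(h, tact, sprintf("down%d_res%d", i, j), P, G)
      h <- rb$y; push(list(kind = "res", bw = rb$bw))
      if (resL[i] %in% cfg$attnResolutions) {
        at <- .attnF(h, sprintf("down%d_attn%d", i, j), P, G, cfg$numHeads)
        h <- at$y; push(list(kind = "lin", bw = at$bw))
      }
    }
    skipStack[[length(skipStack) + 1L]] <- h
    push(list(kind = "save_skip"))
    if (i < L) {
      ds <- .convF(h, sprintf("down%d_ds", i), P, G, stride = 2L)
      h <- ds$y; push(list(kind = "lin", bw = ds$bw))
    }
  }

  m1 <- .resBlockF(h, tact, "mid_res1", P, G)
  h <- m1$y; push(list(kind = "res", bw = m1$bw))
  ma <- .attnF(h, "mid_attn", P, G, cfg$numHeads)
  h <- ma$y; push(list(kind = "lin", bw = ma$bw))
  m2 <- .resBlockF(h, tact, "mid_res2", P, G)
  h <- m2$y; push(list(kind = "res", bw = m2$bw))

  for (i in seq(L, 1L)) {
    sk <- skipStack[[length(skipStack)]]
    skipStack[[length(skipStack)]] <- NULL
    ccur <- dim(h)[3]
    h <- array(c(h, sk), c(dim(h)[1], dim(h)[2], ccur + dim(sk)[3]))
    push(list(kind = "concat", ccur = ccur))
    for (j in seq_len(nres)) {
      rb <- .resBlockF(h, tact, sprintf("up%d_res%d", i, j), P, G)
      h <- rb$y; push(list(kind = "res", bw = rb$bw))
      if (resL[i] %in% cfg$attnResolutions) {
        at <- .attnF(h, sprintf("up%d_attn%d", i, j), P, G, cfg$numHeads)
        h <- at$y; push(list(kind = "lin", bw = at$bw))
      }
    }
    if (i > 1L) {
      u <- .up2F(h, G)
      h <- u$y; push(list(kind = "lin", bw = u$bw))
      uc <- .convF(h, sprintf("up%d_us", i), P, G)
      h <- uc$y; push(list(kind = "lin", bw = uc$bw))
    }
  }

  og <- .gnF(h, "out_gn", P, G)
  os <- .siluF(og$y, G)
  oc <- .convF(os$y, "out_conv", P, G)
  push(list(kind = "lin", bw = og$bw))
  push(list(kind = "lin", bw = os$bw))
  push(list(kind = "lin", bw = oc$bw))
  # note: the last three pushes are in forward order; backward walks them in
  # reverse (oc, os, og) as required.

  out <- matrix(oc$y, dim(oc$y)[1], dim(oc$y)[2])

  bw <- NULL
  if (train) bw <- function(dout) {
    d <- array(dout, c(nrow(dout), ncol(dout), 1L))
    dskips <- list()
    dtact <- numeric(length(tact))
    for (k in rev(seq_along(ops))) {
      op <- ops[[k]]
      if (op$kind == "lin") {
        d <- op$bw(d)
      } else if (op$kind == "res") {
        r <- op$bw(d)
        d <- r$dx
        dtact <- dtact + r$dtact
      } else if (op$kind == "concat") {
        Ctot <- dim(d)[3]
        dskips[[length(dskips) + 1L]] <- d[, , (op$ccur + 1):Ctot, drop = FALSE]
        d <- d[, , seq_len(op$ccur), drop = FALSE]
      } else { # save_skip
        ds <- dskips[[length(dskips)]]
        dskips[[length(dskips)]] <- NULL
        d <- d + ds
      }
    }
    # timestep-embedding path
    d1$bw(s1$bw(d2$bw(sa$bw(dtact))))
    d
  }
  list(out = out, bw = bw)
}

# ---- handle ------------------------------------------------------------

#' Build a denoiser handle
#'
#' Initializes all parameters from `seed` (identical seeds give identical
#' parameters), with residual-branch and output convolutions zero-initialized
#' so the untrained network starts as (approximately) the zero predictor.
#'
#' @param config A configuration from [denoiserConfig()].
#' @param seed Integer seed for the parameter draw.
#' @return A [Denoiser-class] handle.
#' @examples
#' h <- buildDenoiser(denoiserConfig(16, 8, c(1, 2)), seed = 1)
#' @export
buildDenoiser <- function(config, seed = 1L) {
  params <- .initParams(config, seed)
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$ema <- params
  st$opt <- NULL
  st$step <- 0L
  st$evalCount <- 0L
  st$lossLog <- numeric(0)
  new("Denoiser", config = config, state = st)
}

#' Predict the noise content of an image at a timestep
#'
#' One forward evaluation of the network; the handle's evaluation counter is
#' incremented by exactly 1. After training, the EMA parameters are used by
#' default (the inference convention); `useEMA = FALSE` evaluates the raw
#' parameters.
#'
#' @param h A [Denoiser-class].
#' @param xt Noised image ([GrayImage-class], [DiffusionSample-class] or
#'   matrix).
#' @param t Integer timestep.
#' @param useEMA Use the EMA parameter set (default).
#' @return A [NoiseField-class] with the same shape as the input.
#' @export
predictNoise <- function(h, xt, t, useEMA = TRUE) {
  if (is(xt, "DiffusionSample")) xt <- xt@xt
  x <- .asPixelMatrix(xt)
  P <- if (useEMA) h@state$ema else h@state$params
  out <- .unetApply(P, h@config, x, t)$out
  h@state$evalCount <- h@state$evalCount + 1L
  new("NoiseField", values = out, spec = NULL)
}

#' Number of forward evaluations a denoiser has performed
#'
#' Monotone counter incremented on every network evaluation (prediction or
#' training); the hardware-free measure of sampling cost.
#'
#' @param h A [Denoiser-class].
#' @return Integer count.
#' @export
evalCount <- function(h) h@state$evalCount

#' Training-loss history of a denoiser
#' @param h A [Denoiser-class].
#' @return A data.frame with columns `step` and `loss`.
#' @export
trainingLog <- function(h) {
  data.frame(step = seq_along(h@state$lossLog), loss = h@state$lossLog)
}

#' Save / load a denoiser checkpoint
#'
#' Checkpoints store the architecture, raw and EMA parameters, optimizer
#' state and training step, so training is resumable and inference
#' reproducible.
#'
#' @param h A [Denoiser-class].
#' @param path File path.
#' @return `saveCheckpoint` returns `path` invisibly; `loadCheckpoint`
#'   returns a [Denoiser-class].
#' @export
saveCheckpoint <- function(h, path) {
  saveRDS(list(config = h@config, params = h@state$params, ema = h@state$ema,
               opt = h@state$opt, step = h@state$step,
               lossLog = h@state$lossLog), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  st <- new.env(parent = emptyenv())
  st$params <- ck$params
  st$ema <- ck$ema
  st$opt <- ck$opt
  st$step <- ck$step
  st$evalCount <- 0L
  st$lossLog <- ck$lossLog
  new("Denoiser", config = ck$config, state = st)
}
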