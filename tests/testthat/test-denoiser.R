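test_that("sinusoidal timestep embedding behaves like the transformer encoding", {
  e0 <- timeEmbedding(0, 8)
  expect_equal(e0, c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_identical(timeEmbedding(123, 16), timeEmbedding(123, 16))
  expect_error(timeEmbedding(1, 7), "even")
  expect_error(timeEmbedding(-1, 8), ">= 0")
  # injective over the whole chain 0..1000
  M <- t(vapply(0:1000, timeEmbedding, numeric(16), dim = 16))
  expect_false(any(duplicated(M)))
})

test_that("configuration invariants are enforced", {
  expect_error(denoiserConfig(62, 16, c(1, 2, 2)), "divisible")
  expect_error(denoiserConfig(64, 16, c(1, 2), attnResolutions = 13), "subset")
  expect_error(denoiserConfig(64, 16, c(1, 2), attnResolutions = 32,
                              dropout = 0.1), "dropout")
  expect_error(denoiserConfig(64, 15, c(1, 2), attnResolutions = 32,
                              numHeads = 4), "numHeads")
})

test_that("the full-scale architecture builds with 5 levels and a 16 px bottleneck", {
  cfg <- denoiserConfig(256, baseChannels = 128, channelMult = c(1, 1, 2, 3, 4),
                        numResBlocks = 2, attnResolutions = c(32, 16),
                        numHeads = 2)
  expect_equal(256 %/% 2^(length(cfg$channelMult) - 1), 16)
  h <- buildDenoiser(cfg, seed = 1)
  P <- h@state$params
  expect_true(!is.null(P$down5_res1_conv1))
  expect_equal(ncol(P$down5_res1_conv1$W), 512)       # 128 * 4 at the bottom
  expect_true(!is.null(P$down4_attn1_qkv))            # attention at 32 px
  expect_true(!is.null(P$down5_attn1_qkv))            # attention at 16 px
  expect_null(P$down3_attn1_qkv)                      # none at 64 px
  expect_equal(length(P$mid_attn_gn$gamma), 512)
  rm(h); gc(verbose = FALSE)
})

test_that("the denoiser keeps the shape contract and counts evaluations", {
  cfg <- denoiserConfig(64, baseChannels = 16, channelMult = c(1, 2),
                        numResBlocks = 1, attnResolutions = integer(0))
  h <- buildDenoiser(cfg, seed = 1)
  out <- predictNoise(h, matrix(0.1, 64, 64), 300)
  expect_s4_class(out, "NoiseField")
  expect_equal(dim(pixels(out)), c(64L, 64L))
  expect_identical(evalCount(h), 1L)
  invisible(predictNoise(h, matrix(0, 64, 64), 10))
  expect_identical(evalCount(h), 2L)
  expect_error(predictNoise(h, matrix(0, 32, 32), 10), "expects")
})

test_that("identical seeds give identical initial parameters", {
  cfg <- tinyConfig()
  a <- buildDenoiser(cfg, seed = 7)@state$params
  b <- buildDenoiser(cfg, seed = 7)@state$params
  d <- buildDenoiser(cfg, seed = 8)@state$params
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tinyConfig()
  h <- buildDenoiser(cfg, seed = 3)
  # randomize the zero-initialized layers so every path carries signal
  set.seed(1)
  P <- lapply(h@state$params, function(l)
    lapply(l, function(a) { a[] <- rnorm(length(a), sd = 0.2); a }))
  x <- matrix(rnorm(256), 16, 16)
  R <- matrix(rnorm(256), 16, 16)
  G <- new.env(); G$g <- diffAnomaly:::.zeroLike(P)
  fw <- diffAnomaly:::.unetApply(P, cfg, x, 10, G)
  dx <- fw$bw(R)
  numGrad <- function(perturb) {
    e <- 1e-5
    (sum(diffAnomaly:::.unetApply(perturb(e), cfg, x, 10)$out * R) -
       sum(diffAnomaly:::.unetApply(perturb(-e), cfg, x, 10)$out * R)) / (2 * e)
  }
  set.seed(2)
  for (ln in sample(names(P), 10)) {
    pn <- sample(names(P[[ln]]), 1)
    i <- sample(length(P[[ln]][[pn]]), 1)
    num <- numGrad(function(e) {
      P2 <- P; P2[[ln]][[pn]][i] <- P2[[ln]][[pn]][i] + e; P2
    })
    expect_equal(G$g[[ln]][[pn]][i], num, tolerance = 1e-3)
  }
  # input gradient
  i <- 37; e <- 1e-5
  x2 <- x; x2[i] <- x2[i] + e
  lp <- sum(diffAnomaly:::.unetApply(P, cfg, x2, 10)$out * R)
  x2[i] <- x2[i] - 2 * e
  lm <- sum(diffAnomaly:::.unetApply(P, cfg, x2, 10)$out * R)
  expect_equal(dx[i], (lp - lm) / (2 * e), tolerance = 1e-3)
})

test_that("a desk-scale forward+backward pass runs in under a second", {
  p <- readProfile("mini")
  cfg <- profileDenoiserConfig(p)
  h <- buildDenoiser(cfg, seed = 1)
  sched <- linearSchedule(1000L)
  img <- genHealthy(phantomSpec(seed = 3), n = 1)[[1]]
  set.seed(1)
  invisible(trainingStep(h, img, sched, gaussianSpec(1)))  # warm-up
  times <- vapply(1:3, function(i) {
    t0 <- Sys.time()
    invisible(trainingStep(h, img, sched, gaussianSpec(i)))
    as.numeric(Sys.time() - t0)
  }, numeric(1))
  expect_lt(median(times), 1)
})

test_that("checkpoints round-trip the full training state", {
  cfg <- tinyConfig()
  h <- buildDenoiser(cfg, seed = 5)
  sched <- linearSchedule(100L)
  img <- matrix(runif(256, -1, 1), 16, 16)
  set.seed(9)
  for (i in 1:3) trainingStep(h, img, sched, gaussianSpec(i))
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(h, path)
  h2 <- loadCheckpoint(path)
  expect_identical(h2@state$params, h@state$params)
  expect_identical(h2@state$ema, h@state$ema)
  expect_identical(h2@state$step, 3L)
  expect_identical(pixels(predictNoise(h2, img, 50)),
                   pixels(predictNoise(h, img, 50)))
})
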