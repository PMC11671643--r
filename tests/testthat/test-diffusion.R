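sched1000 <- linearSchedule(1000L)

test_that("closed-form forward diffusion is exact in the zero-noise case", {
  x0 <- grayImage(matrix(seq(-1, 1, length.out = 64), 8, 8), "symmetric")
  for (t in c(1L, 300L, 1000L)) {
    xs <- forwardDiffuse(x0, matrix(0, 8, 8), t, sched1000)
    expect_equal(pixels(xs@xt), sqrt(alphaBar(sched1000, t)) * pixels(x0))
  }
})

test_that("forward diffusion matches the scalar oracle at alphaBar = 0.25", {
  s <- quarterSchedule()
  x0 <- grayImage(matrix(1, 4, 4), "symmetric")
  xs <- forwardDiffuse(x0, matrix(1, 4, 4), 2L, s)
  expect_equal(pixels(xs@xt), matrix(0.5 + sqrt(0.75), 4, 4), tolerance = 1e-12)
})

test_that("forward diffusion has the marginal variance 1 - alphaBar", {
  set.seed(7)
  x0 <- grayImage(matrix(0, 64, 64), "symmetric")
  for (t in c(100L, 600L)) {
    draws <- unlist(lapply(1:4, function(i) {
      eps <- pixels(gaussianField(64, 64, seed = 1000 * t + i))
      as.vector(pixels(forwardDiffuse(x0, eps, t, sched1000)@xt))
    }))
    expect_gt(length(draws), 1e4)
    expect_equal(var(draws), 1 - alphaBar(sched1000, t), tolerance = 0.05)
  }
})

test_that("single-evaluation inversion undoes the forward step exactly", {
  set.seed(11)
  for (i in 1:100) {
    x0 <- grayImage(matrix(runif(256, -1, 1), 16, 16), "symmetric")
    eps <- pixels(sampleNoise(simplexSpec(seed = i), 16, 16))
    t <- sample.int(1000L, 1L)
    xs <- forwardDiffuse(x0, eps, t, sched1000)
    rec <- singleStepDenoise(xs, eps, t, sched1000, clip = FALSE)
    expect_lt(max(abs(pixels(rec) - pixels(x0))), 1e-5)
  }
})

test_that("single-step reconstruction handles the trivial predictors", {
  s <- quarterSchedule()
  xt <- grayImage(matrix(0.5 + sqrt(0.75), 4, 4), "free")
  # zero prediction: pure rescale
  expect_equal(pixels(singleStepDenoise(xt, matrix(0, 4, 4), 2L, s, clip = FALSE)),
               pixels(xt) / sqrt(0.25))
  # scalar inversion of the forward example
  rec <- singleStepDenoise(xt, matrix(1, 4, 4), 2L, s)
  expect_equal(pixels(rec), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("clipping bounds the reconstruction into the symmetric range", {
  s <- quarterSchedule()
  xt <- grayImage(matrix(5, 4, 4), "free")
  rec <- singleStepDenoise(xt, matrix(0, 4, 4), 2L, s, clip = TRUE)
  expect_s4_class(rec, "GrayImage")
  expect_equal(rangeTag(rec), "symmetric")
  expect_true(all(pixels(rec) <= 1))
})

test_that("the reverse step matches its scalar oracle and identity limit", {
  # alpha_2 = 0.98, cumulative product 0.25 at t = 2
  s <- new("ScheduleTable", steps = 2L, beta = c(1 - 0.25 / 0.98, 0.02),
           alpha = c(0.25 / 0.98, 0.98), alphaBar = c(0.25 / 0.98, 0.25))
  xt <- grayImage(matrix(1, 4, 4), "free")
  out <- reverseStep(xt, matrix(1, 4, 4), NULL, 2L, s)
  expect_equal(pixels(out),
               matrix((1 - 0.02 / sqrt(0.75)) / sqrt(0.98), 4, 4),
               tolerance = 1e-12)
  expect_equal(pixels(out)[1, 1], 0.9868, tolerance = 1e-4)

  # beta -> 0: the step approaches the identity
  stiny <- linearSchedule(2L, 1e-9, 1e-9)
  out2 <- reverseStep(xt, matrix(0, 4, 4), NULL, 2L, stiny)
  expect_equal(pixels(out2), pixels(xt), tolerance = 1e-6)
})

test_that("forward variance stays bounded for standardized inputs across t", {
  x0 <- grayImage(pixels(gaussianField(64, 64, seed = 5)), "free")
  eps <- pixels(sampleNoise(simplexSpec(seed = 6), 64, 64))
  for (t in c(1L, 250L, 500L, 750L, 1000L)) {
    v <- var(as.vector(pixels(forwardDiffuse(x0, eps, t, sched1000)@xt)))
    expect_gt(v, 0.5)
    expect_lt(v, 1.5)
  }
})

test_that("iterative sampling consumes exactly lambda evaluations", {
  x0 <- grayImage(matrix(0.3, 8, 8), "symmetric")
  den <- countingPredictor(function(xt, t) matrix(0, 8, 8))
  out <- iterativeSample(x0, 0L, den, sched1000)
  expect_identical(attr(den, "counter")$n, 0L)
  expect_equal(pixels(out), pixels(x0))

  den2 <- countingPredictor(function(xt, t) matrix(0, 8, 8))
  invisible(iterativeSample(x0, 37L, den2, sched1000, deterministic = TRUE))
  expect_identical(attr(den2, "counter")$n, 37L)
})

test_that("the deterministic oracle chain recovers the clean image", {
  x0 <- grayImage(matrix(0.7, 8, 8), "symmetric")
  eps <- matrix(0.5, 8, 8)
  lam <- 50L
  xs <- forwardDiffuse(x0, eps, lam, sched1000)
  den <- oraclePredictor(x0, sched1000)
  out <- iterativeSample(xs, lam, den, sched1000, deterministic = TRUE)
  expect_lt(max(abs(pixels(out) - pixels(x0))), 0.05)
})

test_that("stochastic reverse sampling is reproducible under a seed", {
  x0 <- grayImage(matrix(0.2, 8, 8), "symmetric")
  xs <- forwardDiffuse(x0, matrix(1, 8, 8), 20L, sched1000)
  den <- function(xt, t) matrix(0.1, 8, 8)
  a <- iterativeSample(xs, 20L, den, sched1000, seed = 42)
  b <- iterativeSample(xs, 20L, den, sched1000, seed = 42)
  c <- iterativeSample(xs, 20L, den, sched1000, seed = 43)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a), pixels(c)))
})

test_that("shape and range violations are caught", {
  x0 <- grayImage(matrix(0.1, 8, 8), "symmetric")
  expect_error(forwardDiffuse(x0, matrix(0, 4, 4), 10L, sched1000), "shape")
  expect_error(forwardDiffuse(toUnit(x0), matrix(0, 8, 8), 10L, sched1000),
               "symmetric")
  expect_error(forwardDiffuse(x0, matrix(0, 8, 8), 1001L, sched1000),
               "out of range")
  expect_error(iterativeSample(x0, 1001L, function(x, t) x, sched1000),
               "exceeds")
})
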