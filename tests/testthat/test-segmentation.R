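test_that("the error map is the pixel-wise squared difference", {
  a <- grayImage(matrix(0.5, 4, 4), "unit")
  b <- grayImage(matrix(0.5, 4, 4), "unit")
  expect_true(all(pixels(anomalyMap(a, b)) == 0))

  m <- matrix(0.5, 4, 4); m2 <- m; m2[2, 3] <- 0
  em <- pixels(anomalyMap(grayImage(m, "unit"), grayImage(m2, "unit")))
  expect_equal(em[2, 3], 0.25)
  expect_equal(sum(em), 0.25)

  # symmetry
  x <- grayImage(matrix(runif(16), 4, 4), "unit")
  y <- grayImage(matrix(runif(16), 4, 4), "unit")
  expect_equal(pixels(anomalyMap(x, y)), pixels(anomalyMap(y, x)))
  expect_error(anomalyMap(x, grayImage(matrix(0, 2, 2), "unit")), "shape")
  expect_error(anomalyMap(toSymmetric(x), y), "unit")
})

test_that("thresholding is a strict comparison against tau", {
  m <- new("AnomalyMap", values = matrix(c(0.25, 0.31, 0.3, 0), 2, 2),
           lambda = NA_integer_, sampler = "direct", seed = NA_integer_)
  mk <- thresholdMask(m, 0.3)
  expect_identical(as.vector(pixels(mk)), c(FALSE, TRUE, FALSE, FALSE))
  expect_false(any(pixels(thresholdMask(m, 0.5))))
  expect_identical(pixels(thresholdMask(m, 0)), pixels(m) > 0)
  expect_error(thresholdMask(m, -0.1), "tau")
})

test_that("masks shrink pixelwise as tau rises", {
  set.seed(13)
  for (i in 1:20) {
    m <- new("AnomalyMap", values = matrix(runif(256, 0, 0.6), 16, 16),
             lambda = NA_integer_, sampler = "direct", seed = NA_integer_)
    taus <- sort(runif(3, 0, 0.5))
    prev <- pixels(thresholdMask(m, taus[1]))
    for (tau in taus[-1]) {
      cur <- pixels(thresholdMask(m, tau))
      expect_true(all(prev | !cur))  # cur subset of prev
      prev <- cur
    }
  }
})

test_that("postprocessing dilates and keeps the largest 8-connected components", {
  # single pixel -> 3x3 block after dilation
  v <- matrix(FALSE, 9, 9); v[5, 5] <- TRUE
  out <- postprocessMask(v, kernel = 3L, keepK = 1L, minArea = 1L)
  expect_equal(sum(pixels(out)), 9)
  expect_true(all(pixels(out)[4:6, 4:6]))

  # the larger of two well-separated components survives
  v <- matrix(FALSE, 24, 24)
  v[2:3, 2:6] <- TRUE            # area 10
  v[20:21, 20] <- TRUE           # area 2
  out <- postprocessMask(v, kernel = 1L, keepK = 1L, minArea = 1L)
  expect_true(all(pixels(out)[2:3, 2:6]))
  expect_false(any(pixels(out)[20:21, 20]))

  # empty in, empty out
  expect_false(any(pixels(postprocessMask(matrix(FALSE, 5, 5)))))

  # diagonal neighbours form one component (8-connectivity)
  v <- matrix(FALSE, 6, 6); v[2, 2] <- TRUE; v[3, 3] <- TRUE
  out <- postprocessMask(v, kernel = 1L, keepK = 1L, minArea = 2L)
  expect_equal(sum(pixels(out)), 2)

  # min-area filter removes small components
  v <- matrix(FALSE, 8, 8); v[2, 2] <- TRUE
  out <- postprocessMask(v, kernel = 1L, keepK = 1L, minArea = 2L)
  expect_false(any(pixels(out)))
})

test_that("postprocessing is idempotent once its constraints hold", {
  v <- matrix(FALSE, 12, 12); v[4:8, 4:8] <- TRUE
  once <- postprocessMask(v, kernel = 1L, keepK = 1L, minArea = 5L)
  twice <- postprocessMask(once, kernel = 1L, keepK = 1L, minArea = 5L)
  expect_identical(pixels(once), pixels(twice))
})

test_that("single-evaluation segmentation composes the pipeline with one call", {
  sched <- linearSchedule(1000L)
  img <- genHealthy(phantomSpec(size = 32L, seed = 4), n = 1)[[1]]
  oracle <- countingPredictor(oraclePredictor(toSymmetric(img), sched))
  res <- segmentSingle(img, lambda = 300L, denoiser = oracle, sched = sched,
                       noiseSpec = simplexSpec(), tau = 0.3, seed = 8)
  expect_identical(attr(oracle, "counter")$n, 1L)
  # perfect reconstruction of a healthy image: empty mask, zero error
  expect_lt(max(pixels(res$map)), 1e-8)
  expect_false(any(pixels(res$mask)))
  expect_equal(rangeTag(res$recon), "unit")
  expect_warning(
    segmentSingle(img, lambda = 100L, denoiser = oracle, sched = sched,
                  noiseSpec = simplexSpec(), seed = 8),
    "window")
})

test_that("iterative segmentation consumes exactly lambda evaluations", {
  sched <- linearSchedule(1000L)
  img <- genHealthy(phantomSpec(size = 32L, seed = 4), n = 1)[[1]]
  oracle <- countingPredictor(oraclePredictor(toSymmetric(img), sched))
  res <- suppressWarnings(
    segmentIterative(img, lambda = 40L, denoiser = oracle, sched = sched,
                     noiseSpec = simplexSpec(), deterministic = TRUE, seed = 8))
  expect_identical(attr(oracle, "counter")$n, 40L)
  # oracle chain: near-perfect reconstruction, near-empty mask
  expect_lt(max(pixels(res$map)), 0.3)
  expect_false(any(pixels(res$mask)))
})

test_that("segmentation is reproducible under a fixed seed", {
  sched <- linearSchedule(1000L)
  img <- genHealthy(phantomSpec(size = 32L, seed = 4), n = 1)[[1]]
  den <- function(xt, t) 0.5 * xt
  a <- suppressWarnings(segmentIterative(img, 30L, den, sched, seed = 21))
  b <- suppressWarnings(segmentIterative(img, 30L, den, sched, seed = 21))
  expect_identical(pixels(a$mask), pixels(b$mask))
  expect_identical(pixels(a$map), pixels(b$map))
  s1 <- segmentSingle(img, 300L, den, sched, seed = 21)
  s2 <- segmentSingle(img, 300L, den, sched, seed = 21)
  expect_identical(pixels(s1$mask), pixels(s2$mask))
})

test_that("ensemble voting keeps pixels detected at least minVotes times", {
  sched <- linearSchedule(1000L)
  anom <- makeAnomSet(31, 1, size = 32L)[[1]]
  den <- function(xt, t) 0.2 * xt  # crude predictor: noisy, variable masks
  votesOf <- function(minVotes) {
    ensembleSegment(anom$image, lambdas = c(250L, 300L, 350L, 400L),
                    denoiser = den, sched = sched, tau = 0.05,
                    minVotes = minVotes, post = NULL, seed = 17)
  }
  e2 <- votesOf(2L)
  votes <- e2@provenance$votes
  expect_true(max(votes) >= 1)
  # mask is exactly the vote-count comparison
  expect_identical(pixels(e2), votes >= 2L)
  # minVotes = 1 is the union of per-timestep masks
  e1 <- votesOf(1L)
  expect_identical(pixels(e1), votes >= 1L)
  # nesting: raising minVotes never grows the mask
  prev <- pixels(e1)
  for (v in 2:4) {
    cur <- pixels(votesOf(v))
    expect_true(all(prev | !cur))
    prev <- cur
  }
  expect_error(votesOf(5L), "minVotes")
  expect_error(
    ensembleSegment(anom$image, lambdas = integer(0), denoiser = den,
                    sched = sched), "non-empty")
})

test_that("identical per-timestep masks pass through the ensemble unchanged", {
  sched <- linearSchedule(1000L)
  img <- genHealthy(phantomSpec(size = 32L, seed = 4), n = 1)[[1]]
  oracle <- oraclePredictor(toSymmetric(img), sched)
  for (mv in 1:3) {
    e <- ensembleSegment(img, lambdas = c(250L, 300L, 350L), denoiser = oracle,
                         sched = sched, minVotes = mv, post = NULL, seed = 3)
    expect_false(any(pixels(e)))  # all runs reconstruct perfectly
  }
})

test_that("threshold tuning picks the IoU-optimal tau on a labelled split", {
  truth <- matrix(FALSE, 16, 16); truth[5:8, 5:8] <- TRUE
  vals <- matrix(0.05, 16, 16); vals[5:8, 5:8] <- 0.5
  m <- new("AnomalyMap", values = vals, lambda = NA_integer_,
           sampler = "direct", seed = NA_integer_)
  tau <- tuneThreshold(list(m), list(truth), taus = c(0.01, 0.2, 0.6),
                       post = NULL)
  expect_equal(tau, 0.2)
})
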