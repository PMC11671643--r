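test_that("confusion counts partition the pixel grid", {
  g <- matrix(FALSE, 10, 10); g[1:5, 1:2] <- TRUE     # 10 true pixels
  cc <- confusionCounts(g, g)
  expect_equal(cc, c(tp = 10L, fp = 0L, fn = 0L, tn = 90L))
  cc2 <- confusionCounts(matrix(FALSE, 10, 10), g)
  expect_equal(cc2[["fn"]], 10L)
  expect_equal(sum(cc2), 100L)

  p <- matrix(FALSE, 4, 4); p[1:4, 1] <- TRUE
  t4 <- matrix(FALSE, 4, 4); t4[3:4, 1] <- TRUE; t4[3:4, 2] <- TRUE
  expect_equal(confusionCounts(p, t4), c(tp = 2L, fp = 2L, fn = 2L, tn = 10L))
  expect_error(confusionCounts(p, matrix(FALSE, 3, 3)), "shape")
})

test_that("overlap scores match hand-derived values", {
  g <- matrix(FALSE, 8, 8); g[2:4, 2:4] <- TRUE
  s <- segScores(g, g)
  expect_equal(unlist(s[c("dice", "iou", "precision", "recall")]),
               c(dice = 1, iou = 1, precision = 1, recall = 1))

  p <- matrix(FALSE, 8, 8); p[6:8, 6:8] <- TRUE       # disjoint
  s0 <- segScores(p, g)
  expect_equal(unlist(s0[c("dice", "iou", "precision", "recall")]),
               c(dice = 0, iou = 0, precision = 0, recall = 0))

  p <- matrix(FALSE, 4, 4); p[1:4, 1] <- TRUE
  t4 <- matrix(FALSE, 4, 4); t4[3:4, 1:2] <- TRUE
  s2 <- segScores(p, t4)
  expect_equal(s2$iou, 1 / 3)
  expect_equal(s2$dice, 1 / 2)
  expect_equal(s2$precision, 1 / 2)
  expect_equal(s2$recall, 1 / 2)
})

test_that("scores agree with brute-force enumeration on exhaustive 4-pixel masks", {
  combos <- expand.grid(p = 0:15, g = 0:15)
  for (r in seq_len(nrow(combos))) {
    p <- matrix(as.logical(bitwAnd(combos$p[r], c(1L, 2L, 4L, 8L))), 2, 2)
    g <- matrix(as.logical(bitwAnd(combos$g[r], c(1L, 2L, 4L, 8L))), 2, 2)
    s <- segScores(p, g)
    b <- bruteScores(p, g)
    expect_equal(unlist(s[c("dice", "iou", "precision", "recall")]),
                 b, tolerance = 1e-15)
  }
})

test_that("scores agree with brute force on random masks, with dice = 2 iou / (1 + iou)", {
  set.seed(17)
  for (i in 1:20) {
    p <- matrix(runif(256) < 0.3, 16, 16)
    g <- matrix(runif(256) < 0.3, 16, 16)
    s <- segScores(p, g)
    b <- bruteScores(p, g)
    expect_equal(unlist(s[c("dice", "iou", "precision", "recall")]), b)
    expect_equal(s$dice, 2 * s$iou / (1 + s$iou), tolerance = 1e-15)
    expect_gte(s$dice, s$iou)
    expect_true(all(unlist(s[c("dice", "iou", "precision", "recall")]) >= 0))
    expect_true(all(unlist(s[c("dice", "iou", "precision", "recall")]) <= 1))
  }
})

test_that("degenerate masks follow the documented conventions", {
  e <- matrix(FALSE, 4, 4)
  g <- matrix(FALSE, 4, 4); g[1, 1] <- TRUE
  both <- segScores(e, e)
  expect_equal(unlist(both[c("dice", "iou", "precision", "recall")]),
               c(dice = 1, iou = 1, precision = 1, recall = 1))
  miss <- segScores(e, g)
  expect_equal(unlist(miss[c("dice", "iou", "precision", "recall")]),
               c(dice = 0, iou = 0, precision = 0, recall = 0))
})

test_that("pixel AUC is the Mann-Whitney statistic with midranks", {
  g <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  s <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)
  expect_equal(pixelAUC(s, g), 1)            # perfect separation
  expect_equal(pixelAUC(-s, g), 0)

  # exhaustive small case against brute-force pair counting, ties included
  set.seed(5)
  for (i in 1:10) {
    g <- matrix(runif(16) < 0.4, 4, 4)
    if (!any(g) || all(g)) next
    s <- matrix(sample(c(0.1, 0.2, 0.3), 16, replace = TRUE), 4, 4)
    expect_equal(pixelAUC(s, g), bruteAUC(s, g))
  }

  # uninformative scores: AUC near 1/2
  set.seed(6)
  g <- matrix(runif(4096) < 0.2, 64, 64)
  s <- matrix(runif(4096), 64, 64)
  expect_equal(pixelAUC(s, g), 0.5, tolerance = 0.05)

  # invariance under strictly monotone transforms
  expect_equal(pixelAUC(exp(3 * s), g), pixelAUC(s, g))

  expect_warning(a <- pixelAUC(s, matrix(FALSE, 64, 64)), "single-class")
  expect_true(is.na(a))
})

test_that("pixel AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  g <- matrix(runif(400) < 0.3, 20, 20)
  s <- matrix(rnorm(400) + g, 20, 20)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(g), as.vector(s),
                                        quiet = TRUE, direction = "<")))
  expect_equal(pixelAUC(s, g), ref, tolerance = 1e-12)
})

test_that("aggregation reports population mean and spread per metric", {
  one <- data.frame(dice = 0.5, iou = 0.4, precision = 0.6, recall = 0.7)
  agg1 <- aggregateScores(one)
  expect_equal(agg1$mean[agg1$metric == "dice"], 0.5)
  expect_equal(agg1$sd, rep(0, 4))

  two <- data.frame(dice = c(0.2, 0.4))
  agg2 <- aggregateScores(two, metrics = "dice")
  expect_equal(agg2$mean, 0.3)
  expect_equal(agg2$sd, 0.1)  # population sd

  expect_error(aggregateScores(data.frame()), "no scores")
})

test_that("equidistant slice selection spans the annotated range", {
  idx <- equidistantSlices(1, 40, 4)
  expect_equal(idx, c(1L, 14L, 27L, 40L))
  expect_equal(equidistantSlices(10, 10, 4), rep(10L, 4))
  expect_error(equidistantSlices(5, 4), ">=")
})
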