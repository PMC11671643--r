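# Shared fixtures and oracles, built in code at test time.

# Analytic oracle noise predictor: knows the clean image and the schedule,
# and returns the exact noise implied by the marginal forward equation at t.
oraclePredictor <- function(x0sym, sched) {
  x0m <- diffAnomaly::pixels(x0sym)
  function(xt, t) {
    ab <- alphaBar(sched, t)
    (xt - sqrt(ab) * x0m) / sqrt(1 - ab)
  }
}

# Wrap a predictor function with an evaluation counter.
countingPredictor <- function(fn) {
  env <- new.env()
  env$n <- 0L
  f <- function(xt, t) {
    env$n <- env$n + 1L
    fn(xt, t)
  }
  attr(f, "counter") <- env
  f
}

# Tiny denoiser configuration used where only the contract matters.
tinyConfig <- function(size = 16L) {
  denoiserConfig(size, baseChannels = 8L, channelMult = c(1L, 2L),
                 numResBlocks = 1L, attnResolutions = size %/% 2L,
                 numHeads = 2L)
}

# A schedule whose cumulative product hits 0.25 at t = 2 (handy for the
# scalar arithmetic examples).
quarterSchedule <- function() linearSchedule(2L, 0.5, 0.5)

# Brute-force metric references (pixel and pair enumeration).
bruteScores <- function(p, g) {
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  if (tp + fp + fn == 0) return(c(dice = 1, iou = 1, precision = 1, recall = 1))
  c(dice = 2 * tp / (2 * tp + fp + fn),
    iou = tp / (tp + fp + fn),
    precision = if (tp + fp == 0) 0 else tp / (tp + fp),
    recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

bruteAUC <- function(s, g) {
  pos <- s[g]; neg <- s[!g]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Small anomalous phantom set with ground truth.
makeAnomSet <- function(seed, n, offset = 0.4, size = 64L) {
  sp <- phantomSpec(size = size, seed = seed, anomaly = list(offset = offset))
  hl <- genHealthy(sp, n = n)
  lapply(seq_len(n), function(i) injectAnomaly(hl[[i]], sp, seed = seed * 1000 + i))
}
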