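test_that("defaultNumWindows matches the (p/w) log p rule", {
  expect_equal(defaultNumWindows(2000, 200), 76L)
  expect_equal(defaultNumWindows(20000, 2000), 99L)
  expect_equal(defaultNumWindows(200000, 2000), 1221L)
  expect_equal(defaultNumWindows(2000000, 2000), 14509L)
  # single window covers everything per draw
  expect_equal(defaultNumWindows(100, 100), as.integer(round(log(100))))
  expect_error(defaultNumWindows(10, 11), "1 <= w <= p")
})

test_that("sliding blocks partition consecutively, last absorbs the remainder", {
  blocks <- crossLeverage:::.slidingBlocks(10L, 3L)
  expect_equal(blocks, list(1:3, 4:6, 7:10))
  expect_equal(crossLeverage:::.slidingBlocks(6L, 3L), list(1:3, 4:6))
  expect_equal(crossLeverage:::.slidingBlocks(5L, 9L), list(1:5))
})

test_that("sliding window with w = p reproduces exactCLS bit for bit", {
  X <- randomGenotypeMatrix(15, 60, seed = 1)
  y <- rbinom(15, 1L, 0.4)
  ex <- exactCLS(X, y)
  sl <- slidingWindowCLS(X, y, w = 60)
  expect_identical(sl@scores, ex@scores)
  expect_identical(sl@leverageY, ex@leverageY)
  expect_equal(sl@method, "sliding")
})

test_that("sliding window concatenates per-block scores in original order", {
  X <- randomGenotypeMatrix(10, 50, seed = 2)
  y <- rbinom(10, 1L, 0.5)
  sl <- suppressWarnings(slidingWindowCLS(X, y, w = 20))
  # block structure {1..20}, {21..50}: each block equals its own exact run
  b1 <- exactCLS(X[, 1:20], y)@scores
  b2 <- exactCLS(X[, 21:50], y)@scores
  expect_identical(sl@scores, c(b1, b2))
  expect_true(all(coverage(sl) == 1L))
})

test_that("window width below ceiling(n log n) warns but still computes", {
  X <- randomGenotypeMatrix(30, 40, seed = 3)
  y <- rbinom(30, 1L, 0.5)
  expect_warning(slidingWindowCLS(X, y, w = 10), "recommended")
  expect_silent2 <- function(expr) expect_warning(expr, NA)
  # w = p emits no width warning even when p < n log n
  expect_silent2(slidingWindowCLS(X, y, w = 40))
})

test_that("random window with w = p reproduces exactCLS bit for bit", {
  X <- randomGenotypeMatrix(15, 60, seed = 4)
  y <- rbinom(15, 1L, 0.4)
  ex <- exactCLS(X, y)
  rw <- randomWindowCLS(X, y, w = 60, R = 1, seed = 5)
  expect_identical(rw@scores, ex@scores)
  expect_true(all(coverage(rw) == 1L))
})

test_that("random windows are reproducible from the seed and error when w > p", {
  X <- randomGenotypeMatrix(12, 80, seed = 6)
  y <- rbinom(12, 1L, 0.5)
  a <- suppressWarnings(randomWindowCLS(X, y, w = 20, R = 10, seed = 7))
  b <- suppressWarnings(randomWindowCLS(X, y, w = 20, R = 10, seed = 7))
  expect_identical(a@scores, b@scores)
  expect_identical(a@coverage, b@coverage)
  expect_error(randomWindowCLS(X, y, w = 81), "exceeds p")
})

test_that("random window merge keeps the max-magnitude signed score and counts coverage", {
  X <- randomGenotypeMatrix(12, 30, seed = 8)
  y <- rbinom(12, 1L, 0.5)
  R <- 8L
  rw <- suppressWarnings(
    randomWindowCLS(X, y, w = 10, R = R, seed = 9,
                    stopOnFullCoverage = FALSE))
  expect_equal(sum(coverage(rw)), R * 10L)
  # brute-force replay of the same seeded window draws
  set.seed(9)
  best <- numeric(30)
  key <- rep(-Inf, 30)
  cov <- integer(30)
  for (r in seq_len(R)) {
    idx <- sort(sample.int(30L, 10L))
    sc <- exactCLS(X[, idx, drop = FALSE], y)@scores
    take <- abs(sc) > key[idx]
    best[idx[take]] <- sc[take]
    key[idx[take]] <- abs(sc[take])
    cov[idx] <- cov[idx] + 1L
  }
  expect_identical(rw@scores, best)
  expect_identical(rw@coverage, cov)
})

test_that("uncovered variables score 0 with a warning; early stop on full coverage", {
  X <- randomGenotypeMatrix(10, 40, seed = 10)
  y <- rbinom(10, 1L, 0.5)
  rw <- withCallingHandlers(
    randomWindowCLS(X, y, w = 10, R = 1, seed = 11),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_equal(sum(coverage(rw) == 0L), 30L)
  expect_true(all(rw@scores[coverage(rw) == 0L] == 0))
  muffleWidth <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("recommended", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  expect_warning(muffleWidth(randomWindowCLS(X, y, w = 10, R = 1,
                                             seed = 11)),
                 "never drawn")
  # early stopping reports fewer iterations than R when coverage completes
  rw2 <- suppressWarnings(
    randomWindowCLS(X, y, w = 40, R = 50, seed = 12))
  expect_equal(rw2@params$iterations, 1L)
})

test_that("window methods honour the streaming contract", {
  X <- randomGenotypeMatrix(12, 55, seed = 13)
  y <- rbinom(12, 1L, 0.5)
  cs <- countingSource(matrixSource(X, y))
  suppressWarnings(slidingWindowCLS(cs, w = 20))
  st <- fetchStats(cs)
  # one fetch per block; widest block at most 2w - 1; each variable once
  expect_equal(st$totalColumns, 55)
  expect_lte(st$maxWidth, 2 * 20 - 1)
  expect_equal(st$nFetches, 2L)

  cs2 <- countingSource(matrixSource(X, y))
  suppressWarnings(randomWindowCLS(cs2, w = 10, R = 5, seed = 14,
                                   stopOnFullCoverage = FALSE))
  st2 <- fetchStats(cs2)
  expect_equal(st2$maxWidth, 10)
  expect_equal(st2$totalColumns, 50)
})

test_that("random window coverage at the default R matches the coupon-collector rate", {
  # At p = 2000, w = 200, R = 76 each variable is missed with probability
  # (1 - w/p)^R, so full coverage happens in roughly exp(-p (1-w/p)^R)
  # of runs; the observed fraction should sit within Monte-Carlo error.
  ds <- simulateScenario("s1", n = 60, p = 2000, seed = 100)
  R <- defaultNumWindows(2000, 200)
  expect_equal(R, 76L)
  runs <- 100
  full <- logical(runs)
  for (t in seq_len(runs)) {
    rw <- suppressWarnings(
      randomWindowCLS(ds@X, ds@y, w = 200, R = R, seed = t,
                      stopOnFullCoverage = FALSE))
    full[t] <- all(coverage(rw) > 0L)
  }
  expected <- exp(-2000 * (1 - 0.1)^76)
  se <- sqrt(expected * (1 - expected) / runs)
  expect_lt(abs(mean(full) - expected), 3 * se + 0.02)
})

test_that("sliding windows at study scale track exact scores and recover the interaction", {
  # S1 scenario, p = 2000, w = 200: the per-window scores are not the
  # exact scores, but rank similarly and retain the two interacting
  # SNPs in the top q = 575 for the median replicate.
  reps <- 200
  found <- integer(reps)
  for (t in seq_len(reps)) {
    ds <- simulateScenario("s1", n = 120, p = 2000, seed = 3000 + t)
    sl <- suppressWarnings(slidingWindowCLS(ds@X, ds@y, w = 200))
    found[t] <- countRecovered(topQ(sl@scores, 575, "largest"),
                               ds@truth)
  }
  expect_gte(median(found), 2)

  ds <- simulateScenario("s1", n = 120, p = 2000, seed = 3001)
  ex <- exactCLS(ds@X, ds@y)@scores
  sl <- suppressWarnings(slidingWindowCLS(ds@X, ds@y, w = 200))@scores
  expect_gt(cor(ex, sl, method = "spearman"), 0)
})
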