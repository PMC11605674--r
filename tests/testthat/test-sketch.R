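test_that("defaultSketchDim follows ceil(ceil(n ln n) / eps^2)", {
  expect_equal(defaultSketchDim(120, 0.5), 2300L)
  expect_equal(defaultSketchDim(120, 0.2), 14375L)
  expect_equal(defaultSketchDim(120, 0.1), 57500L)
  expect_equal(defaultSketchDim(120, 1), 575L)
  expect_error(defaultSketchDim(120, 0), "positive")
  expect_error(defaultSketchDim(120, -0.1), "positive")
})

test_that("embedding has exactly s unit-scaled nonzeros per column", {
  plan <- sketchPlan(r = 50L, s = 5L, seed = 3L)
  Pi <- buildEmbedding(200L, plan)
  expect_equal(dim(Pi), c(50L, 200L))
  nnzPerCol <- diff(Pi@p)
  expect_true(all(nnzPerCol == 5L))
  expect_true(all(abs(Pi@x) == 1 / sqrt(5)))
  # unit column norms
  expect_equal(as.numeric(Matrix::colSums(Pi^2)), rep(1, 200))
})

test_that("s = 1 reproduces the single +/-1 CountSketch structure", {
  plan <- sketchPlan(r = 3L, s = 1L, seed = 4L)
  Pi <- buildEmbedding(5L, plan)
  expect_true(all(diff(Pi@p) == 1L))
  expect_true(all(Pi@x %in% c(-1, 1)))
  # applying to a vector yields signed sums of coordinate subsets that
  # partition the coordinates across the r output rows
  x <- c(1, 10, 100, 1000, 10000)
  v <- as.numeric(Pi %*% x)
  signs <- Pi@x
  rows <- Pi@i + 1L
  manual <- vapply(1:3, function(r) sum((signs * x)[rows == r]),
                   numeric(1))
  expect_equal(v, manual)
})

test_that("the embedding is reproducible from its seed and isometric in expectation", {
  plan <- sketchPlan(r = 40L, s = 4L, seed = 5L)
  expect_identical(buildEmbedding(30L, plan), buildEmbedding(30L, plan))
  expect_error(sketchPlan(r = 3L, s = 5L, seed = 1L), "1 <= s <= r")
  # E[||Pi x||^2] = ||x||^2 for unit x
  set.seed(6)
  x <- rnorm(30)
  x <- x / sqrt(sum(x^2))
  norms <- vapply(1:300, function(s) {
    Pi <- buildEmbedding(30L, sketchPlan(r = 40L, s = 4L, seed = s))
    sum(as.numeric(Pi %*% x)^2)
  }, numeric(1))
  expect_lt(abs(mean(norms) - 1), 3 * sd(norms) / sqrt(300))
})

test_that("identity embedding reproduces exact scores", {
  X <- randomGenotypeMatrix(20, 120, seed = 7)
  y <- rbinom(20, 1L, 0.4)
  ex <- exactCLS(X, y)
  sk <- sketchCLS(X, y, Pi = Matrix::Diagonal(121))
  expect_lt(max(abs(sk@scores - ex@scores)), 1e-10)
  expect_equal(sk@leverageY, ex@leverageY, tolerance = 1e-10)
  expect_equal(sk@method, "sketch")
})

test_that("sketchCLS is deterministic given (data, plan) and independent of block size", {
  X <- randomGenotypeMatrix(15, 400, seed = 8)
  y <- rbinom(15, 1L, 0.4)
  plan <- sketchPlan(n = 15, epsilon = 0.6, seed = 9L)
  a <- sketchCLS(X, y, plan = plan)
  b <- sketchCLS(X, y, plan = plan)
  expect_identical(a@scores, b@scores)
  d <- sketchCLS(X, y, plan = plan, blockSize = 37L)
  expect_equal(d@scores, a@scores, tolerance = 1e-12)
})

test_that("rank-deficient sketches and undersized targets raise advisory errors", {
  # duplicated samples make the sketched matrix rank deficient
  X <- randomGenotypeMatrix(10, 300, seed = 10)
  Xdup <- rbind(X, X)
  ydup <- rep(rbinom(10, 1L, 0.5), 2)
  plan <- sketchPlan(n = 20, epsilon = 0.9, seed = 11L)
  expect_error(sketchCLS(Xdup, ydup, plan = plan), "rank deficient")
  expect_error(
    sketchCLS(X, rbinom(10, 1L, 0.5),
              Pi = buildEmbedding(301L, sketchPlan(r = 5L, s = 1L,
                                                   seed = 1L))),
    "below n")
})

test_that("r >= p~ falls back to the exact computation with a warning", {
  X <- randomGenotypeMatrix(20, 50, seed = 12)
  y <- rbinom(20, 1L, 0.4)
  plan <- sketchPlan(n = 20, epsilon = 0.5, seed = 13L) # r = 240 > 51
  expect_warning(sk <- sketchCLS(X, y, plan = plan), "exact")
  expect_identical(sk@scores, exactCLS(X, y)@scores)
})

test_that("the additive accuracy guarantee holds across embedding seeds", {
  # p~ = 1201 sketched down to r = 120: a coarse epsilon = 1 embedding
  # must still keep every score within epsilon of exact.
  ds <- simulateScenario("s1", n = 40, p = 1200, seed = 14)
  ex <- exactCLS(ds@X, ds@y)@scores
  eps <- 1
  dev <- vapply(1:40, function(s) {
    sk <- sketchCLS(ds@X, ds@y,
                    plan = sketchPlan(n = 40, epsilon = eps, seed = s))
    max(abs(sk@scores - ex))
  }, numeric(1))
  expect_gte(mean(dev <= eps), 0.9)
})

test_that("sketchCLS replays the source exactly twice with bounded blocks", {
  X <- randomGenotypeMatrix(15, 500, seed = 15)
  y <- rbinom(15, 1L, 0.4)
  cs <- countingSource(matrixSource(X, y))
  plan <- sketchPlan(n = 15, epsilon = 0.6, seed = 16L)
  invisible(sketchCLS(cs, plan = plan, blockSize = 100L))
  st <- fetchStats(cs)
  expect_equal(st$totalColumns, 2 * 500)
  expect_lte(st$maxWidth, 100L)
})
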