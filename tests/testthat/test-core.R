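test_that("buildAugmented stacks variables as rows and appends y verbatim", {
  A <- buildAugmented(diag(2), c(1, 0))
  expect_equal(A@values, rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(nVariables(A), 2L)
  expect_equal(nSamples(A), 2L)

  d <- toyDataset(seed = 1)
  A <- buildAugmented(d@X, d@y)
  expect_equal(dim(A@values), c(61L, 16L))
  expect_equal(as.numeric(A@values[61, ]),
               c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(responseVector(A), d@y)
})

test_that("buildAugmented rejects bad input with informative errors", {
  expect_error(buildAugmented(diag(3), c(1, 0)), "3 rows.*length 2")
  X <- diag(3)
  X[2, 1] <- NaN
  expect_error(buildAugmented(X, c(1, 0, 0)), "non-finite.*row 2")
  expect_error(buildAugmented(diag(3), c(1, 0, NA)), "non-finite.*position 3")
})

test_that("orthonormalBasis normalizes already-orthogonal columns", {
  M <- cbind(c(2, 0, 0), c(0, 3, 0))
  B <- orthonormalBasis(M)
  expect_equal(B@rank, 2L)
  # up to column sign
  expect_equal(abs(B@Q), cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(crossprod(B@Q), diag(2), tolerance = 1e-12)
})

test_that("orthonormalBasis handles rank deficiency via a truncated SVD", {
  v <- c(1, 2, 3, 4)
  M <- cbind(v, 2 * v) # rank 1 from two columns
  B <- orthonormalBasis(M)
  expect_equal(B@rank, 1L)
  P <- B@Q %*% t(B@Q)
  Porc <- tcrossprod(v) / sum(v^2)
  expect_equal(P, Porc, tolerance = 1e-10)
  # projector idempotence
  expect_equal(P %*% P, P, tolerance = 1e-10)
})

test_that("orthonormal columns span the input (projector reproduces it)", {
  set.seed(4)
  M <- matrix(rnorm(200 * 20), 200, 20)
  B <- orthonormalBasis(M)
  expect_equal(crossprod(B@Q), diag(20), tolerance = 1e-10)
  expect_equal(B@Q %*% crossprod(B@Q, M), M, tolerance = 1e-8)
})

test_that("exactCLS matches the pseudoinverse hat-matrix oracle", {
  cases <- list(
    list(n = 20, p = 300, seed = 11),
    list(n = 25, p = 599, seed = 12),
    list(n = 12, p = 40, seed = 13))
  for (cs in cases) {
    X <- randomGenotypeMatrix(cs$n, cs$p, cs$seed)
    y <- rbinom(cs$n, 1L, 0.4)
    H <- hatMatrixOracle(X, y)
    res <- exactCLS(X, y)
    expect_lt(max(abs(res@scores - H[seq_len(cs$p), cs$p + 1L])), 1e-8)
    expect_equal(res@leverageY, H[cs$p + 1L, cs$p + 1L],
                 tolerance = 1e-10)
    expect_true(all(res@coverage == 1L))
  }
})

test_that("exactCLS agrees with the oracle when y lies in a variable's span", {
  X <- diag(5) * 3
  y <- c(1, 0, 0, 0, 0) # y is in the span of variable 1
  H <- hatMatrixOracle(X, y)
  res <- exactCLS(X, y)
  expect_equal(res@scores, H[1:5, 6], tolerance = 1e-10)
})

test_that("projector identity: sum of c_i^2 equals h_y (1 - h_y)", {
  X <- randomGenotypeMatrix(30, 500, seed = 21)
  y <- rbinom(30, 1L, 0.3)
  res <- exactCLS(X, y)
  hy <- res@leverageY
  expect_lt(abs(sum(res@scores^2) - hy * (1 - hy)), 1e-8)
  expect_true(hy >= 0 && hy <= 1)
  expect_true(all(abs(res@scores) <= 1 + 1e-12))
})

test_that("scores obey the Cauchy-Schwarz bound |c_i| <= sqrt(h_i h_y)", {
  X <- randomGenotypeMatrix(15, 80, seed = 22)
  y <- rbinom(15, 1L, 0.5)
  H <- hatMatrixOracle(X, y)
  res <- exactCLS(X, y)
  hi <- diag(H)[seq_len(80)]
  expect_true(all(abs(res@scores) <=
                    sqrt(hi * res@leverageY) + 1e-10))
})

test_that("exactCLS is invariant to scaling and sample permutation, equivariant to variable permutation", {
  X <- randomGenotypeMatrix(18, 120, seed = 23)
  y <- rbinom(18, 1L, 0.4)
  base <- exactCLS(X, y)@scores
  # scale invariance (column space unchanged)
  expect_equal(exactCLS(2.5 * X, 2.5 * y)@scores, base,
               tolerance = 1e-10)
  # sample permutation invariance
  perm <- sample(18)
  expect_equal(exactCLS(X[perm, ], y[perm])@scores, base,
               tolerance = 1e-10)
  # variable permutation equivariance
  vperm <- sample(120)
  expect_equal(exactCLS(X[, vperm], y)@scores, base[vperm],
               tolerance = 1e-10)
})

test_that("minNormOLS returns the pseudoinverse solution", {
  expect_equal(minNormOLS(diag(4), c(3, -1, 2, 0)), c(3, -1, 2, 0))
  # symmetry of the min-norm solution on an underdetermined system
  expect_equal(minNormOLS(matrix(c(1, 1), 1, 2), 2), c(1, 1))
  # interpolation in p >> n
  set.seed(31)
  X <- matrix(rnorm(30 * 300), 30, 300)
  y <- rnorm(30)
  beta <- minNormOLS(X, y)
  expect_lt(max(abs(X %*% beta - y)), 1e-8)
})

test_that("clsOLSGap equals the brute-force max difference and vanishes in the orthogonal case", {
  # orthogonal variables, y orthogonal to all of them
  X <- cbind(c(1, 0, 0), c(0, 1, 0))
  y <- c(0, 0, 1)
  g <- clsOLSGap(X, y)
  expect_equal(g$gap, 0, tolerance = 1e-12)

  X <- randomGenotypeMatrix(20, 150, seed = 41)
  y <- rbinom(20, 1L, 0.4)
  g <- clsOLSGap(X, y)
  expect_equal(g$gap,
               max(abs(minNormOLS(X, y) - exactCLS(X, y)@scores)),
               tolerance = 1e-12)
  expect_true(is.finite(g$alignmentEta) && g$alignmentEta > 0)
})
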