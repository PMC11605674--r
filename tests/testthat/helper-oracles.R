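# Independent oracles used across the suite.

# Hat matrix of [X, y]' computed via an SVD pseudoinverse projector,
# independent of the package's QR/backsolve path.
hatMatrixOracle <- function(X, y) {
  M <- t(cbind(X, y))
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1L]
  U <- sv$u[, sv$d > tol, drop = FALSE]
  U %*% t(U)
}

# Textbook Pearson correlation, one column at a time.
bruteCorrelation <- function(X, y) {
  apply(X, 2, function(x) {
    xc <- x - mean(x)
    yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  })
}

randomGenotypeMatrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rbinom(n * p, 2L, 0.3), n, p)
}
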