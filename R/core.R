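#' Build the augmented matrix \eqn{\tilde{X} = [X, y]^T}
#'
#' Stacks the variables as rows and appends the response as the last
#' row, yielding the \eqn{\tilde{p} \times n} matrix whose hat matrix
#' carries the cross leverage scores in its last column. No centering,
#' scaling or intercept is applied; a binary response is used as numeric
#' 0/1 and a real-valued response is accepted unchanged.
#'
#' @param X numeric matrix, samples by variables (n x p).
#' @param y numeric response vector of length n.
#' @return an [AugmentedMatrix].
#' @examples
#' A <- buildAugmented(diag(2), c(1, 0))
#' nVariables(A)
#' @export
buildAugmented <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop(sprintf("dimension mismatch: X has %d rows but y has length %d",
                 nrow(X), length(y)))
  }
  if (nrow(X) < 2L) stop("need at least n = 2 samples")
  if (ncol(X) < 1L) stop("need at least one variable")
  bad <- which(!is.finite(X))
  if (length(bad)) {
    stop(sprintf("non-finite entry in X at row %d, column %d",
                 row(X)[bad[1L]], col(X)[bad[1L]]))
  }
  bad <- which(!is.finite(y))
  if (length(bad)) {
    stop(sprintf("non-finite entry in y at position %d", bad[1L]))
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(X)))
  values <- rbind(t(X), y, deparse.level = 0)
  dimnames(values) <- NULL
  new("AugmentedMatrix",
      values = values,
      variableIds = ids,
      n = nrow(X),
      p = ncol(X))
}

#' @describeIn nSamples samples of an augmented matrix.
#' @export
setMethod("nSamples", "AugmentedMatrix", function(x) x@n)

#' @describeIn nSamples variables of an augmented matrix.
#' @export
setMethod("nVariables", "AugmentedMatrix", function(x) x@p)

#' @describeIn nSamples identifiers of an augmented matrix.
#' @export
setMethod("variableIds", "AugmentedMatrix", function(x) x@variableIds)

#' @describeIn nSamples response row of an augmented matrix.
#' @export
setMethod("responseVector", "AugmentedMatrix", function(x) {
  as.numeric(x@values[x@p + 1L, ])
})

setMethod("show", "AugmentedMatrix", function(object) {
  cat(sprintf("AugmentedMatrix: p~ = %d rows (p = %d variables + response), n = %d samples\n",
              object@p + 1L, object@p, object@n))
})

.basisFromMatrix <- function(M) {
  qrM <- qr(M)
  full <- min(dim(M))
  if (qrM$rank == full) {
    Q <- qr.Q(qrM)
    return(new("OrthonormalBasis", Q = Q, rank = as.integer(full),
               toleranceUsed = 0))
  }
  sv <- svd(M, nv = 0)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1L]
  keep <- sv$d > tol
  new("OrthonormalBasis",
      Q = sv$u[, keep, drop = FALSE],
      rank = as.integer(sum(keep)),
      toleranceUsed = tol)
}

#' @describeIn orthonormalBasis basis of an augmented matrix.
#' @export
setMethod("orthonormalBasis", "AugmentedMatrix", function(x, ...) {
  .basisFromMatrix(x@values)
})

#' @describeIn orthonormalBasis basis of a plain matrix.
#' @export
setMethod("orthonormalBasis", "matrix", function(x, ...) {
  if (!all(is.finite(x))) stop("matrix must be finite")
  .basisFromMatrix(x)
})

setMethod("show", "OrthonormalBasis", function(object) {
  cat(sprintf("OrthonormalBasis: %d x %d, rank %d (sv cutoff %.3g)\n",
              nrow(object@Q), ncol(object@Q), object@rank,
              object@toleranceUsed))
})

# Last column of the hat matrix H = QQ' of a p~ x n matrix, without
# materializing Q when the matrix has full column rank: with M[, piv] = QR,
# H e_y = M[, piv] (R'R)^{-1} (row p~ of M[, piv])', applied by two
# triangular back-substitutions. Falls back to a truncated SVD basis when
# the numerical rank is below n.
.hatColumnY <- function(M) {
  ptilde <- nrow(M)
  n <- ncol(M)
  qrM <- qr(M)
  if (qrM$rank == n && ptilde >= n) {
    R <- qr.R(qrM)
    piv <- qrM$pivot
    my <- M[ptilde, piv]
    z <- backsolve(R, backsolve(R, my, transpose = TRUE))
    cfull <- as.numeric(M[, piv, drop = FALSE] %*% z)
  } else {
    sv <- svd(M, nv = 0)
    tol <- max(dim(M)) * .Machine$double.eps * sv$d[1L]
    U <- sv$u[, sv$d > tol, drop = FALSE]
    cfull <- as.numeric(U %*% U[ptilde, ])
  }
  cfull
}

#' Exact cross leverage scores
#'
#' Computes \eqn{c_{i\tilde{p}} = \langle Q_{i\cdot}, Q_{\tilde{p}\cdot}
#' \rangle} for every variable \eqn{i}, where \eqn{Q} is an orthonormal
#' basis of the column space of \eqn{\tilde{X} = [X, y]^T}. These are
#' the off-diagonal hat-matrix entries \eqn{H[i, \tilde{p}]} linking
#' each variable to the response: a variable whose score is far from
#' zero exerts leverage on the response within the multivariate subspace
#' spanned by the data, which is how interacting variables without
#' marginal effects become visible.
#'
#' @param X numeric matrix (n x p), an [AugmentedMatrix], or a
#'   [VariableSource-class].
#' @param y numeric response of length n (omit when `X` already carries
#'   the response).
#' @return a [CLSResult] with `method = "exact"` and coverage 1 for
#'   every variable.
#' @examples
#' d <- toyDataset(seed = 1)
#' res <- exactCLS(d@X, d@y)
#' head(clsScores(res))
#' @export
exactCLS <- function(X, y = NULL) {
  A <- if (is(X, "AugmentedMatrix")) {
    if (!is.null(y)) stop("y must be NULL when X is an AugmentedMatrix")
    X
  } else if (is(X, "VariableSource")) {
    if (!is.null(y)) stop("y must be NULL when X is a VariableSource")
    buildAugmented(fetchVariables(X, seq_len(X@p)), responseVector(X))
  } else {
    buildAugmented(X, y)
  }
  cfull <- .hatColumnY(A@values)
  ptilde <- A@p + 1L
  new("CLSResult",
      scores = cfull[-ptilde],
      leverageY = cfull[ptilde],
      method = "exact",
      params = list(),
      coverage = rep(1L, A@p),
      variableIds = A@variableIds)
}

setMethod("show", "CLSResult", function(object) {
  p <- length(object@scores)
  cat(sprintf("CLSResult (%s): %d variables, h_y = %.4g\n",
              object@method, p, object@leverageY))
  top <- order(-abs(object@scores))[seq_len(min(5L, p))]
  cat("  largest |score|:",
      paste(sprintf("%s=%.3g", object@variableIds[top],
                    object@scores[top]), collapse = ", "), "\n")
  if (any(object@coverage == 0L)) {
    cat(sprintf("  %d variables never covered (score 0)\n",
                sum(object@coverage == 0L)))
  }
})

#' Minimum-norm ordinary least squares solution
#'
#' Returns the smallest-norm minimizer of \eqn{\|X\beta - y\|_2^2}, i.e.
#' the pseudoinverse solution \eqn{X^+ y}. In the under-determined
#' \eqn{p \ge n} regime this interpolates the response. Each cross
#' leverage score approximates the corresponding coefficient of this
#' solution up to a small additive error when the row space is well
#' aligned with the response; [clsOLSGap()] reports the discrepancy.
#'
#' @param X numeric matrix, n x p.
#' @param y numeric response of length n.
#' @return numeric coefficient vector of length p.
#' @export
minNormOLS <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop(sprintf("dimension mismatch: X has %d rows but y has length %d",
                 nrow(X), length(y)))
  }
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1L]
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  as.numeric(sv$v %*% (dinv * crossprod(sv$u, y)))
}

#' Gap between cross leverage scores and the min-norm OLS solution
#'
#' Diagnostic for the theoretical link between the two quantities:
#' computes `max_i |beta_i - c_i|` together with the alignment ratio
#' \eqn{h_y^2 / \sum_i c_i^2} (small values indicate that the row space
#' is well aligned with the response, the regime in which the gap is
#' provably small). The gap is reported, not asserted against a bound.
#'
#' @param X numeric matrix, n x p.
#' @param y numeric response of length n.
#' @return list with components `gap`, `alignmentEta` and `leverageY`.
#' @export
clsOLSGap <- function(X, y) {
  beta <- minNormOLS(X, y)
  res <- exactCLS(X, y)
  sumc2 <- sum(res@scores^2)
  hy <- res@leverageY
  list(gap = max(abs(beta - res@scores)),
       alignmentEta = if (sumc2 > 0) hy^2 / sumc2 else Inf,
       leverageY = hy)
}
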