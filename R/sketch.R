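#' Default sketch target dimension
#'
#' Returns \eqn{r = \lceil \lceil n \ln n \rceil / \varepsilon^2
#' \rceil}, the number of rows of the sparse embedding needed for an
#' additive score accuracy of `epsilon`.
#'
#' @param n number of samples.
#' @param epsilon accuracy parameter, > 0.
#' @return integer target dimension.
#' @examples
#' defaultSketchDim(120, 0.5) # 2300
#' defaultSketchDim(120, 0.1) # 57500
#' @export
defaultSketchDim <- function(n, epsilon) {
  if (n < 2) stop("need n >= 2")
  if (epsilon <= 0) stop("epsilon must be positive")
  as.integer(ceiling(ceiling(n * log(n)) / epsilon^2))
}

#' Construct a sketching plan
#'
#' Bundles the parameters of the sparse oblivious subspace embedding:
#' target dimension `r` (defaulting to [defaultSketchDim()]), nonzeros
#' per column `s` (defaulting to `max(1, ceiling(log2(n)))`), the
#' accuracy `epsilon` and the RNG seed.
#'
#' @param n number of samples (needed when `r` or `s` is left `NULL`).
#' @param epsilon accuracy parameter.
#' @param r target dimension; overrides `epsilon` when given.
#' @param s nonzeros per column of the embedding.
#' @param seed RNG seed for the embedding.
#' @return a [SketchPlan].
#' @export
sketchPlan <- function(n = NULL, epsilon = 0.5, r = NULL, s = NULL,
                       seed = 1L) {
  if (is.null(r)) {
    if (is.null(n)) stop("supply n to derive r from epsilon")
    r <- defaultSketchDim(n, epsilon)
  }
  if (is.null(s)) {
    if (is.null(n)) stop("supply n to derive s")
    s <- max(1L, as.integer(ceiling(log2(n))))
  }
  new("SketchPlan", r = as.integer(r), s = as.integer(s),
      epsilon = as.numeric(epsilon), seed = as.integer(seed))
}

setMethod("show", "SketchPlan", function(object) {
  cat(sprintf("SketchPlan: r = %d, s = %d, epsilon = %s, seed = %s\n",
              object@r, object@s, format(object@epsilon),
              format(object@seed)))
})

#' Build the sparse subspace embedding operator
#'
#' Constructs \eqn{\Pi \in R^{r \times \tilde{p}}} with exactly `s`
#' nonzeros of value \eqn{\pm 1/\sqrt{s}} per column. The `r` rows are
#' split into `s` contiguous blocks and one row per block is chosen
#' uniformly (OSNAP-style placement, which avoids within-column
#' collisions); signs are uniform. With `s = 1` this is the classical
#' single-nonzero CountSketch structure. Columns have unit Euclidean
#' norm, so \eqn{E[\Pi^T\Pi] = I}.
#'
#' @param pTilde number of columns (variables plus the response row).
#' @param plan a [SketchPlan]; its seed makes the operator reproducible.
#' @return a sparse `Matrix::dgCMatrix` of dimension `r x pTilde`.
#' @export
buildEmbedding <- function(pTilde, plan) {
  stopifnot(is(plan, "SketchPlan"))
  pTilde <- as.integer(pTilde)
  if (pTilde < 1L) stop("pTilde must be at least 1")
  r <- plan@r
  s <- plan@s
  if (is.na(s)) stop("plan has no sparsity parameter s")
  if (s > r) stop(sprintf("s = %d exceeds r = %d", s, r))
  if (!is.na(plan@seed)) set.seed(plan@seed)
  bounds <- floor(seq(0L, r, length.out = s + 1L))
  sizes <- diff(bounds)
  # one uniform row inside each of the s blocks, per column
  u <- matrix(stats::runif(s * pTilde), nrow = s)
  rows <- as.integer(bounds[-(s + 1L)] + ceiling(u * sizes))
  signs <- sample(c(-1, 1), s * pTilde, replace = TRUE)
  Matrix::sparseMatrix(
    i = rows,
    j = rep(seq_len(pTilde), each = s),
    x = signs / sqrt(s),
    dims = c(r, pTilde))
}

#' Sketched cross leverage scores
#'
#' Two-pass streaming approximation with user-set accuracy: pass 1
#' accumulates the sketched matrix \eqn{\tilde{X}^\star = \Pi\tilde{X}
#' \in R^{r \times n}} block by block; its QR decomposition yields the
#' triangular factor \eqn{R^\star}. Pass 2 forms each row of
#' \eqn{\Omega = \tilde{X} R^{\star-1}} by triangular back-substitution
#' (the response row \eqn{\Omega_{\tilde{p}\cdot}} first) and returns
#' \eqn{\hat{c}_{i\tilde{p}} = \langle \Omega_{i\cdot},
#' \Omega_{\tilde{p}\cdot} \rangle}. The dense working state is the
#' r-by-n accumulator plus one block, independent of `p`. The scores
#' satisfy \eqn{|c_{i\tilde{p}} - \hat{c}_{i\tilde{p}}| \le \varepsilon}
#' with high probability over the embedding.
#'
#' @param x matrix (n x p) or [VariableSource-class].
#' @param y response vector (omit when `x` carries it).
#' @param plan a [SketchPlan]; when its `r` is at least
#'   \eqn{\tilde{p}}, sketching cannot shrink the problem and the exact
#'   computation is used instead (with a warning).
#' @param Pi optional explicit embedding operator (`r x pTilde`),
#'   overriding `plan`'s random construction.
#' @param blockSize number of variables fetched per block.
#' @return a [SketchedCLSResult].
#' @export
sketchCLS <- function(x, y = NULL, plan = NULL, Pi = NULL,
                      blockSize = 1024L) {
  src <- asVariableSource(x, y)
  n <- src@n
  p <- src@p
  ptilde <- p + 1L
  yv <- responseVector(src)
  if (!length(yv)) stop("source carries no response")
  if (is.null(Pi)) {
    if (is.null(plan)) stop("supply a SketchPlan or an explicit operator Pi")
    if (plan@r >= ptilde) {
      warning(sprintf(
        "target dimension r = %d is not below p~ = %d; computing exact scores instead",
        plan@r, ptilde))
      ex <- exactCLS(x, y)
      return(new("SketchedCLSResult",
                 scores = ex@scores, leverageY = ex@leverageY,
                 method = "sketch",
                 params = list(r = plan@r, s = plan@s,
                               epsilon = plan@epsilon, seed = plan@seed,
                               fallback = "exact"),
                 coverage = ex@coverage, variableIds = ex@variableIds,
                 plan = plan, rStarCondition = NA_real_))
    }
    Pi <- buildEmbedding(ptilde, plan)
  } else {
    Pi <- as(Pi, "CsparseMatrix")
    if (ncol(Pi) != ptilde) {
      stop(sprintf("Pi has %d columns but p~ = %d", ncol(Pi), ptilde))
    }
    if (is.null(plan)) {
      plan <- new("SketchPlan", r = nrow(Pi), s = NA_integer_,
                  epsilon = NA_real_, seed = NA_integer_)
    }
  }
  r <- nrow(Pi)
  if (r < n) {
    stop(sprintf("target dimension r = %d is below n = %d; increase r",
                 r, n))
  }
  blockSize <- max(1L, as.integer(blockSize))
  blocks <- split(seq_len(p), ceiling(seq_len(p) / blockSize))

  # pass 1: accumulate the sketched matrix
  A <- matrix(0, r, n)
  for (block in blocks) {
    B <- fetchVariables(src, block)
    A <- A + as.matrix(Pi[, block, drop = FALSE] %*% t(B))
  }
  A <- A + as.matrix(Pi[, ptilde, drop = FALSE] %*% matrix(yv, 1L, n))

  qrA <- qr(A)
  if (qrA$rank < n) {
    stop("sketched matrix is rank deficient; increase r or use a different seed")
  }
  Rstar <- qr.R(qrA)
  piv <- qrA$pivot
  cond <- kappa(Rstar, exact = FALSE)

  # pass 2: response row of Omega first, then blockwise scores
  omegaY <- backsolve(Rstar, yv[piv], transpose = TRUE)
  scores <- numeric(p)
  for (block in blocks) {
    B <- fetchVariables(src, block)
    Ot <- backsolve(Rstar, B[piv, , drop = FALSE], transpose = TRUE)
    scores[block] <- as.numeric(crossprod(Ot, omegaY))
  }

  new("SketchedCLSResult",
      scores = scores,
      leverageY = sum(omegaY^2),
      method = "sketch",
      params = list(r = r, s = plan@s, epsilon = plan@epsilon,
                    seed = plan@seed, blockSize = blockSize),
      coverage = rep(1L, p),
      variableIds = src@variableIds,
      plan = plan,
      rStarCondition = cond)
}
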