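#' Recommended selection size \eqn{q = \lceil n \ln n \rceil}
#'
#' Oversampling the sample size by a log factor ensures, by a coupon
#' collector argument, that the selected submatrix preserves the full
#' rank n of the data with good probability.
#'
#' @param n number of samples.
#' @return integer selection size.
#' @examples
#' defaultQ(120) # 575
#' defaultQ(16)  # 45
#' @export
defaultQ <- function(n) {
  if (n < 2) stop("need n >= 2")
  as.integer(ceiling(n * log(n)))
}

#' Select the top-q variables by score
#'
#' Ranks variables by signed score (`mode = "largest"`) or by absolute
#' score (`mode = "absolute"`, the default: informative scores can be
#' negative when the absence of an interaction drives the response).
#' Ties are broken deterministically by ascending variable index.
#'
#' @param scores numeric score vector, or a [CLSResult].
#' @param q number of variables to select; `q > p` selects all with a
#'   warning.
#' @param mode ranking key.
#' @return a [SelectionResult].
#' @export
topQ <- function(scores, q, mode = c("absolute", "largest")) {
  mode <- match.arg(mode)
  if (is(scores, "CLSResult")) scores <- scores@scores
  scores <- as.numeric(scores)
  p <- length(scores)
  if (p == 0L) stop("empty score vector")
  q <- as.integer(q)
  if (q < 1L) stop("q must be at least 1")
  if (q > p) {
    warning(sprintf("q = %d exceeds p = %d; selecting all variables", q, p))
    q <- p
  }
  key <- if (mode == "absolute") abs(scores) else scores
  ord <- order(-key, seq_len(p))
  new("SelectionResult",
      indices = ord[seq_len(q)],
      q = q,
      mode = mode,
      scoresUsed = scores)
}

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: q = %d of %d variables (mode %s)\n",
              object@q, length(object@scoresUsed), object@mode))
  k <- min(10L, object@q)
  cat("  top:", paste(object@indices[seq_len(k)], collapse = " "),
      if (object@q > k) "..." else "", "\n")
})

#' Marginal correlation scores
#'
#' Pearson correlation of every variable with the response, the
#' univariate baseline that cross leverage scores are compared against.
#' Variables interacting without marginal effects can have correlation
#' exactly zero and are invisible to this ranking. Zero-variance
#' variables (or a zero-variance response) score 0 with a warning.
#'
#' @param X numeric matrix, samples by variables.
#' @param y numeric response.
#' @return numeric vector of length p.
#' @export
correlationScores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop(sprintf("dimension mismatch: X has %d rows but y has length %d",
                 nrow(X), length(y)))
  }
  if (nrow(X) < 2L) stop("need at least n = 2 samples")
  if (stats::sd(y) == 0) {
    warning("response has zero variance; all correlation scores are 0")
    return(numeric(ncol(X)))
  }
  sc <- suppressWarnings(as.numeric(stats::cor(X, y)))
  bad <- !is.finite(sc)
  if (any(bad)) {
    warning(sprintf("%d zero-variance variables scored 0", sum(bad)))
    sc[bad] <- 0
  }
  sc
}

#' Expected recovery under uniform selection
#'
#' Mean number of the `kImportant` truly important variables contained
#' in a uniform random selection of `q` out of `p` variables (the
#' hypergeometric mean `k * q / p`) — the gray-line baseline of the
#' recovery curves.
#'
#' @param kImportant number of important variables.
#' @param q selection size.
#' @param p total number of variables.
#' @return scalar expected count.
#' @export
uniformExpectedRecovery <- function(kImportant, q, p) {
  if (kImportant < 0 || kImportant > p) stop("need 0 <= kImportant <= p")
  if (q < 1 || q > p) stop("need 1 <= q <= p")
  kImportant * q / p
}
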