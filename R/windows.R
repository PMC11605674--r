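#' Recommended number of random windows
#'
#' Coupon-collector style default \eqn{R = \mathrm{round}((p/w) \ln p)}:
#' with windows of `w` uniformly drawn variables, this many draws cover
#' every variable at least once with good probability.
#'
#' @param p number of variables.
#' @param w window width.
#' @return integer number of windows.
#' @examples
#' defaultNumWindows(2000, 200)    # 76
#' defaultNumWindows(2000000, 2000) # 14509
#' @export
defaultNumWindows <- function(p, w) {
  if (w < 1 || w > p) stop("need 1 <= w <= p")
  as.integer(round((p / w) * log(p)))
}

# Partition 1..p into consecutive blocks of width w; the last block
# absorbs the remainder (width w .. 2w-1) instead of forming a runt
# block that would be rank deficient.
.slidingBlocks <- function(p, w) {
  if (w >= p) return(list(seq_len(p)))
  nb <- p %/% w
  starts <- (seq_len(nb) - 1L) * w + 1L
  ends <- c(starts[-1L] - 1L, p)
  Map(seq.int, starts, ends)
}

.checkWindowWidth <- function(w, n, p) {
  if (w < 1L) stop("window width w must be at least 1")
  rec <- ceiling(n * log(n))
  if (w < rec && w < p) {
    warning(sprintf(
      "window width w = %d is below the recommended ceiling(n log n) = %d; submatrices may be rank deficient",
      w, rec))
  }
}

#' Sliding-window cross leverage scores
#'
#' Partitions the variables into consecutive blocks of width `w` (the
#' last block absorbs any remainder), runs the exact computation on each
#' block with the response appended, and concatenates the per-block
#' scores in the original variable order. Only one block is resident at
#' a time, so arbitrarily large `p` can be processed from a file-backed
#' source. With `w >= p` the single window reproduces [exactCLS()]
#' exactly.
#'
#' @param x matrix (n x p) or [VariableSource-class].
#' @param y response vector (omit when `x` carries it).
#' @param w window width in variables; recommended at least
#'   `ceiling(n * log(n))` to avoid rank-deficient submatrices (a
#'   warning is emitted below that).
#' @return a [CLSResult] with `method = "sliding"`.
#' @export
slidingWindowCLS <- function(x, y = NULL, w) {
  src <- asVariableSource(x, y)
  n <- src@n
  p <- src@p
  if (p < 1L) stop("empty variable source")
  yv <- responseVector(src)
  if (!length(yv)) stop("source carries no response")
  w <- as.integer(w)
  .checkWindowWidth(w, n, p)
  blocks <- .slidingBlocks(p, w)
  scores <- numeric(p)
  for (block in blocks) {
    B <- fetchVariables(src, block)
    res <- exactCLS(B, yv)
    scores[block] <- res@scores
  }
  hy <- if (length(blocks) == 1L) {
    res@leverageY
  } else {
    NA_real_
  }
  # h_y differs per window; report the exact value only in the
  # single-window case, otherwise the last window's value.
  if (is.na(hy)) hy <- res@leverageY
  new("CLSResult",
      scores = scores,
      leverageY = hy,
      method = "sliding",
      params = list(w = w, nBlocks = length(blocks)),
      coverage = rep(1L, p),
      variableIds = src@variableIds)
}

#' Random-window cross leverage scores
#'
#' Repeatedly draws `w` distinct variables uniformly at random, runs the
#' exact computation on the drawn submatrix with the response appended,
#' and merges scores across windows by keeping, for every variable, the
#' score of largest magnitude seen so far (the signed value is
#' retained; set `merge = "signed"` to keep the largest signed value
#' instead). Stops after `R` windows, or earlier once every variable has
#' been covered when `stopOnFullCoverage` is set. Variables never drawn
#' keep score 0 and coverage 0, with a warning.
#'
#' @param x matrix (n x p) or [VariableSource-class].
#' @param y response vector (omit when `x` carries it).
#' @param w window width; must satisfy `w <= p`. When `w == p` each
#'   window is the full variable set and the result reproduces
#'   [exactCLS()] exactly.
#' @param R maximum number of windows; defaults to
#'   [defaultNumWindows()].
#' @param seed optional RNG seed for the window draws.
#' @param stopOnFullCoverage stop early once every variable was drawn.
#' @param merge `"absolute"` (keep the score of largest magnitude) or
#'   `"signed"`.
#' @return a [CLSResult] with `method = "random"` and per-variable
#'   coverage counts.
#' @export
randomWindowCLS <- function(x, y = NULL, w, R = NULL, seed = NULL,
                            stopOnFullCoverage = TRUE,
                            merge = c("absolute", "signed")) {
  merge <- match.arg(merge)
  src <- asVariableSource(x, y)
  n <- src@n
  p <- src@p
  if (p < 1L) stop("empty variable source")
  yv <- responseVector(src)
  if (!length(yv)) stop("source carries no response")
  w <- as.integer(w)
  if (w > p) stop(sprintf("window width w = %d exceeds p = %d", w, p))
  .checkWindowWidth(w, n, p)
  if (is.null(R)) R <- defaultNumWindows(p, w)
  R <- as.integer(R)
  if (R < 1L) stop("R must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  scores <- numeric(p)
  keyBest <- rep(-Inf, p)
  cov <- integer(p)
  iters <- 0L
  for (r in seq_len(R)) {
    idx <- if (w == p) seq_len(p) else sort(sample.int(p, w))
    B <- fetchVariables(src, idx)
    res <- exactCLS(B, yv)
    sc <- res@scores
    key <- if (merge == "absolute") abs(sc) else sc
    take <- key > keyBest[idx] | cov[idx] == 0L
    scores[idx[take]] <- sc[take]
    keyBest[idx[take]] <- key[take]
    cov[idx] <- cov[idx] + 1L
    iters <- r
    if (stopOnFullCoverage && all(cov > 0L)) break
  }
  uncovered <- sum(cov == 0L)
  if (uncovered > 0L) {
    warning(sprintf(
      "%d of %d variables were never drawn in %d windows; their scores are 0",
      uncovered, p, iters))
  }
  new("CLSResult",
      scores = scores,
      leverageY = res@leverageY,
      method = "random",
      params = list(w = w, R = R, seed = seed, iterations = iters,
                    merge = merge,
                    stopOnFullCoverage = stopOnFullCoverage),
      coverage = cov,
      variableIds = src@variableIds)
}
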