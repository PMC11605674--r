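# Fixed part of the toy dataset: 16 observations of the four
# interacting binary variables, constructed so that y = 1 exactly when
# x1 = x2 = 1 or x3 = x4 = 1, while cor(x1, y) = cor(x2, y) = 0.
.toyFixedBlock <- matrix(c(
  1, 1, 0, 1,
  1, 1, 1, 0,
  0, 0, 1, 1,
  0, 0, 1, 1,
  1, 0, 0, 1,
  1, 0, 1, 0,
  0, 1, 0, 1,
  0, 1, 1, 0,
  1, 1, 0, 1,
  1, 1, 1, 0,
  0, 0, 1, 1,
  0, 0, 1, 1,
  1, 0, 0, 1,
  1, 0, 1, 0,
  0, 1, 0, 1,
  0, 1, 1, 0), ncol = 4L, byrow = TRUE)

.toyResponse <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0)

#' The 16 x 60 binary toy dataset
#'
#' A small worked counterexample to correlation screening: 16
#' observations of 60 binary variables where the response is 1 exactly
#' when `x1 = x2 = 1` or `x3 = x4 = 1`. The first four columns and the
#' response are a fixed, balanced design under which `cor(x1, y)` and
#' `cor(x2, y)` are exactly zero — correlation ranking can never find
#' x1 and x2 — while their cross leverage scores are nonzero. Columns 5
#' to 60 are fair coin flips.
#'
#' @param seed optional RNG seed for the 56 noise columns.
#' @return a [SimulatedDataset] with `n = 16`, `p = 60` and truth
#'   `{1, 2, 3, 4}`.
#' @examples
#' d <- toyDataset(seed = 1)
#' cor(d@X[, 1], d@y) # exactly 0
#' @export
toyDataset <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(.toyFixedBlock)
  noise <- matrix(sample(c(0, 1), n * 56L, replace = TRUE), n, 56L)
  X <- cbind(.toyFixedBlock, noise)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  # deterministic limit of the logistic model: y = (x1 & x2) | (x3 & x4)
  model <- interactionModel(
    beta0 = -Inf,
    terms = list(snpTerm(c(1L, 2L), Inf), snpTerm(c(3L, 4L), Inf)))
  new("SimulatedDataset",
      X = X,
      y = .toyResponse,
      mafs = colMeans(X) / 2,
      truth = 1:4,
      model = model,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
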