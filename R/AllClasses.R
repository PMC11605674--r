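#' @import methods
NULL

#' Augmented data matrix \eqn{\tilde{X} = [X, y]^T}
#'
#' Container for the transposed, response-augmented data matrix used for
#' cross leverage score computation in the \eqn{p \gg n} regime. Rows
#' \eqn{1, \dots, p} hold the variables (e.g., SNP dosages), row
#' \eqn{\tilde{p} = p + 1} holds the response verbatim: no centering,
#' scaling or intercept is applied.
#'
#' @slot values numeric matrix of dimension \eqn{\tilde{p} \times n}.
#' @slot variableIds character vector of length \eqn{p}.
#' @slot n integer, number of samples (columns).
#' @slot p integer, number of variables (rows minus the response row).
#'
#' @seealso [buildAugmented()], [exactCLS()]
#' @export
setClass("AugmentedMatrix",
  representation(
    values = "matrix",
    variableIds = "character",
    n = "integer",
    p = "integer"
  )
)

setValidity("AugmentedMatrix", function(object) {
  msg <- character()
  if (nrow(object@values) != object@p + 1L)
    msg <- c(msg, "values must have p + 1 rows (variables plus response)")
  if (ncol(object@values) != object@n)
    msg <- c(msg, "values must have n columns")
  if (length(object@variableIds) != object@p)
    msg <- c(msg, "variableIds must have length p")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all entries must be finite")
  if (length(msg)) msg else TRUE
})

#' Orthonormal basis of the column space of an augmented matrix
#'
#' Holds a matrix \eqn{Q} with orthonormal columns spanning the column
#' space of \eqn{\tilde{X}}, obtained by thin QR decomposition, or by an
#' SVD with a singular-value cutoff when \eqn{\tilde{X}} is numerically
#' rank deficient. The hat matrix is \eqn{H = QQ^T}.
#'
#' @slot Q numeric matrix, \eqn{\tilde{p} \times k} with orthonormal columns.
#' @slot rank integer, the numerical rank \eqn{k \le n}.
#' @slot toleranceUsed numeric, singular-value cutoff applied (0 when the
#'   QR path was taken on a full-rank matrix).
#'
#' @seealso [orthonormalBasis()]
#' @export
setClass("OrthonormalBasis",
  representation(
    Q = "matrix",
    rank = "integer",
    toleranceUsed = "numeric"
  )
)

setValidity("OrthonormalBasis", function(object) {
  msg <- character()
  if (ncol(object@Q) != object@rank)
    msg <- c(msg, "Q must have rank columns")
  if (length(object@toleranceUsed) != 1L)
    msg <- c(msg, "toleranceUsed must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Cross leverage score result
#'
#' Per-variable cross leverage scores \eqn{c_{i\tilde{p}}}, i.e., the
#' off-diagonal hat-matrix entries \eqn{H[i, \tilde{p}]} between each
#' variable and the appended response, plus the leverage of the response
#' itself and provenance metadata.
#'
#' @slot scores numeric vector of length \eqn{p}.
#' @slot leverageY numeric scalar, \eqn{h_y = \langle Q_{\tilde{p}\cdot},
#'   Q_{\tilde{p}\cdot}\rangle} (or its approximation).
#' @slot method character tag: `"exact"`, `"sliding"`, `"random"` or
#'   `"sketch"`.
#' @slot params list of method parameters, including any RNG seed.
#' @slot coverage integer vector: how many windows/computations each
#'   variable entered (all ones for exact, sliding and sketch).
#' @slot variableIds character vector of length \eqn{p}.
#'
#' @seealso [exactCLS()], [slidingWindowCLS()], [randomWindowCLS()],
#'   [sketchCLS()]
#' @export
setClass("CLSResult",
  representation(
    scores = "numeric",
    leverageY = "numeric",
    method = "character",
    params = "list",
    coverage = "integer",
    variableIds = "character"
  )
)

setValidity("CLSResult", function(object) {
  msg <- character()
  p <- length(object@scores)
  if (length(object@coverage) != p)
    msg <- c(msg, "coverage must match scores in length")
  if (length(object@variableIds) != p)
    msg <- c(msg, "variableIds must match scores in length")
  if (any(object@coverage < 0L))
    msg <- c(msg, "coverage counts must be nonnegative")
  if (length(object@leverageY) != 1L || !is.finite(object@leverageY))
    msg <- c(msg, "leverageY must be a finite scalar")
  if (!all(is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(object@method) != 1L)
    msg <- c(msg, "method must be a single tag")
  if (length(msg)) msg else TRUE
})

#' Sparse subspace embedding plan
#'
#' Parameters of the sparse oblivious subspace embedding
#' \eqn{\Pi \in R^{r \times \tilde{p}}} used by the sketching
#' approximation: each column carries exactly `s` nonzeros of value
#' \eqn{\pm 1/\sqrt{s}}, placed OSNAP-style with one uniform row per
#' contiguous block of rows.
#'
#' @slot r integer, target dimension (rows of \eqn{\Pi}).
#' @slot s integer, nonzeros per column.
#' @slot epsilon numeric, accuracy parameter of the score guarantee
#'   (`NA` when the operator was supplied directly).
#' @slot seed integer RNG seed (`NA` when the operator was supplied).
#'
#' @seealso [sketchPlan()], [buildEmbedding()], [sketchCLS()]
#' @export
setClass("SketchPlan",
  representation(
    r = "integer",
    s = "integer",
    epsilon = "numeric",
    seed = "integer"
  )
)

setValidity("SketchPlan", function(object) {
  msg <- character()
  if (length(object@r) != 1L || is.na(object@r) || object@r < 1L)
    msg <- c(msg, "r must be a positive integer")
  if (length(object@s) != 1L)
    msg <- c(msg, "s must be a scalar")
  if (!is.na(object@s) && (object@s < 1L || object@s > object@r))
    msg <- c(msg, "s must satisfy 1 <= s <= r")
  if (length(object@epsilon) != 1L)
    msg <- c(msg, "epsilon must be a scalar")
  if (!is.na(object@epsilon) && object@epsilon <= 0)
    msg <- c(msg, "epsilon must be positive")
  if (length(msg)) msg else TRUE
})

#' Sketched cross leverage score result
#'
#' A [CLSResult] produced by the sketching approximation, carrying the
#' embedding plan and a condition estimate of the sketched triangular
#' factor \eqn{R^\star}.
#'
#' @slot plan the [SketchPlan] used.
#' @slot rStarCondition numeric, condition-number estimate of
#'   \eqn{R^\star}.
#'
#' @seealso [sketchCLS()]
#' @export
setClass("SketchedCLSResult",
  contains = "CLSResult",
  representation(
    plan = "SketchPlan",
    rStarCondition = "numeric"
  )
)

#' Boolean interaction model for simulated responses
#'
#' Generative truth for the genotype simulator: a logistic model whose
#' linear predictor is \eqn{\beta_0 + \sum_j \beta_j M_j}, where each
#' \eqn{M_j} is a conjunction of dominant SNP indicators (genotype
#' \eqn{\ge 1}), optionally negated.
#'
#' @slot beta0 numeric intercept.
#' @slot terms list; each element is a list with components `vars`
#'   (integer variable indices), `coef` (numeric \eqn{\beta_j}) and
#'   `negated` (logical, one flag per literal).
#'
#' @seealso [interactionModel()], [snpTerm()], [simulateResponse()]
#' @export
setClass("InteractionModel",
  representation(
    beta0 = "numeric",
    terms = "list"
  )
)

setValidity("InteractionModel", function(object) {
  msg <- character()
  if (length(object@beta0) != 1L || is.na(object@beta0))
    msg <- c(msg, "beta0 must be a non-missing scalar")
  for (k in seq_along(object@terms)) {
    tm <- object@terms[[k]]
    if (!is.list(tm) || !all(c("vars", "coef", "negated") %in% names(tm))) {
      msg <- c(msg, sprintf("term %d must have vars, coef and negated", k))
      next
    }
    if (anyDuplicated(tm$vars))
      msg <- c(msg, sprintf("term %d has duplicated variable indices", k))
    if (length(tm$negated) != length(tm$vars))
      msg <- c(msg, sprintf("term %d: negated must match vars in length", k))
    if (length(tm$coef) != 1L || is.na(tm$coef))
      msg <- c(msg, sprintf("term %d: coef must be a non-missing scalar", k))
  }
  if (length(msg)) msg else TRUE
})

#' Simulated SNP dataset
#'
#' Genotype matrix with entries in \{0, 1, 2\}, binary response, the
#' minor allele frequencies used, the set of truly important variables
#' and the generating [InteractionModel].
#'
#' @slot X numeric matrix, samples by variables.
#' @slot y numeric response vector.
#' @slot mafs numeric vector of per-SNP minor allele frequencies.
#' @slot truth integer vector of important variable indices.
#' @slot model the generating [InteractionModel].
#' @slot seed integer RNG seed used (`NA` if none was set).
#'
#' @seealso [simulateScenario()], [toyDataset()]
#' @export
setClass("SimulatedDataset",
  representation(
    X = "matrix",
    y = "numeric",
    mafs = "numeric",
    truth = "integer",
    model = "InteractionModel",
    seed = "integer"
  )
)

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  if (length(object@y) != nrow(object@X))
    msg <- c(msg, "y must have one entry per row of X")
  if (length(object@mafs) != ncol(object@X))
    msg <- c(msg, "mafs must have one entry per column of X")
  if (any(object@truth < 1L) || any(object@truth > ncol(object@X)))
    msg <- c(msg, "truth indices must lie in 1..p")
  if (length(msg)) msg else TRUE
})

#' Variable selection result
#'
#' The ordered indices of the top-\eqn{q} variables under a ranking of
#' scores (signed or by absolute value), with deterministic tie-breaking
#' by ascending variable index.
#'
#' @slot indices integer vector, selected variables in ranking order.
#' @slot q integer, effective selection size (`min(q, p)`).
#' @slot mode character, `"largest"` or `"absolute"`.
#' @slot scoresUsed numeric, the raw score vector that was ranked.
#'
#' @seealso [topQ()]
#' @export
setClass("SelectionResult",
  representation(
    indices = "integer",
    q = "integer",
    mode = "character",
    scoresUsed = "numeric"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (anyDuplicated(object@indices))
    msg <- c(msg, "indices must be distinct")
  if (length(object@indices) != object@q)
    msg <- c(msg, "indices must have length q")
  if (!object@mode %in% c("largest", "absolute"))
    msg <- c(msg, "mode must be 'largest' or 'absolute'")
  if (length(msg)) msg else TRUE
})

#' Variable sources: block access to a samples-by-variables matrix
#'
#' `VariableSource` is the streaming access layer consumed by the window
#' and sketching methods: it exposes the dimensions, variable
#' identifiers, the response vector, and block fetches of arbitrary
#' variable subsets via [fetchVariables()]. `MatrixSource` backs the
#' interface with an in-memory matrix; `TSVSource` reads column subsets
#' of a delimited text file on demand so that only the requested block
#' is ever resident; `CountingSource` wraps another source and records
#' fetch statistics (used to verify streaming contracts).
#'
#' @slot n integer, number of samples.
#' @slot p integer, number of variables.
#' @slot variableIds character vector of length `p`.
#' @slot response numeric response vector (length `n`, or length 0 when
#'   the backing format carries no phenotype).
#'
#' @aliases MatrixSource TSVSource CountingSource
#' @seealso [matrixSource()], [tsvSource()], [countingSource()],
#'   [fetchVariables()]
#' @export
setClass("VariableSource",
  representation(
    "VIRTUAL",
    n = "integer",
    p = "integer",
    variableIds = "character",
    response = "numeric"
  )
)

#' @export
setClass("MatrixSource",
  contains = "VariableSource",
  representation(X = "matrix")
)

#' @export
setClass("TSVSource",
  contains = "VariableSource",
  representation(
    path = "character",
    columns = "character",
    sep = "character"
  )
)

#' @export
setClass("CountingSource",
  contains = "VariableSource",
  representation(
    inner = "VariableSource",
    stats = "environment"
  )
)
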