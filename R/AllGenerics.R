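#' Extract scores from a result object
#'
#' @param x a [CLSResult] or [SelectionResult].
#' @return numeric vector of cross leverage scores.
#' @export
setGeneric("clsScores", function(x) standardGeneric("clsScores"))

#' @describeIn clsScores scores of a CLS result.
#' @export
setMethod("clsScores", "CLSResult", function(x) {
  stats::setNames(x@scores, x@variableIds)
})

#' Coverage counts: how many computations each variable entered
#'
#' @param x a [CLSResult].
#' @return integer vector of length `p`.
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @describeIn coverage coverage of a CLS result.
#' @export
setMethod("coverage", "CLSResult", function(x) {
  stats::setNames(x@coverage, x@variableIds)
})

#' Leverage of the response row
#'
#' @param x a [CLSResult].
#' @return scalar \eqn{h_y \in [0, 1]} (approximate methods may exceed
#'   the exact value slightly).
#' @export
setGeneric("leverageY", function(x) standardGeneric("leverageY"))

#' @describeIn leverageY response leverage of a CLS result.
#' @export
setMethod("leverageY", "CLSResult", function(x) x@leverageY)

#' Selected variable indices
#'
#' @param x a [SelectionResult].
#' @return integer vector in ranking order.
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @describeIn selectedIndices indices of a selection.
#' @export
setMethod("selectedIndices", "SelectionResult", function(x) x@indices)

#' Dimensions and identifiers of a variable source
#'
#' @param x a [VariableSource-class], [AugmentedMatrix] or result object.
#' @return `nSamples`/`nVariables` return a count; `variableIds` a
#'   character vector; `responseVector` the numeric response.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname nSamples
#' @export
setGeneric("nVariables", function(x) standardGeneric("nVariables"))

#' @rdname nSamples
#' @export
setGeneric("variableIds", function(x) standardGeneric("variableIds"))

#' @rdname nSamples
#' @export
setGeneric("responseVector", function(x) standardGeneric("responseVector"))

#' Fetch a block of variables from a source
#'
#' Returns the samples-by-variables submatrix for the requested variable
#' indices, in the requested order. File-backed sources read only the
#' requested columns.
#'
#' @param x a [VariableSource-class].
#' @param indices integer vector of variable indices (1-based).
#' @return numeric matrix with `nSamples(x)` rows and `length(indices)`
#'   columns.
#' @export
setGeneric("fetchVariables", function(x, indices) {
  standardGeneric("fetchVariables")
})

#' Orthonormal basis of the column space
#'
#' Computes a matrix \eqn{Q} with orthonormal columns spanning the
#' column space of the augmented matrix, via thin QR decomposition when
#' the matrix is numerically full rank, and via an SVD truncated at
#' `tol = max(dim) * eps * sigma_max` otherwise.
#'
#' @param x an [AugmentedMatrix] or a plain numeric matrix.
#' @param ... unused.
#' @return an [OrthonormalBasis].
#' @export
setGeneric("orthonormalBasis", function(x, ...) {
  standardGeneric("orthonormalBasis")
})

#' Important variables of a generative model
#'
#' @param x an [InteractionModel] or [SimulatedDataset].
#' @return sorted integer vector of the variable indices appearing in
#'   terms with nonzero coefficient.
#' @export
setGeneric("truthVariables", function(x) standardGeneric("truthVariables"))
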