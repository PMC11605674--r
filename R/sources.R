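#' Construct an in-memory variable source
#'
#' @param X numeric matrix or data frame, samples by variables.
#' @param y optional numeric response of length `nrow(X)`.
#' @return a `MatrixSource`.
#' @seealso [fetchVariables()], [tsvSource()]
#' @export
matrixSource <- function(X, y = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(X)))
  if (is.null(y)) y <- numeric(0) else {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) {
      stop(sprintf("response length %d does not match %d samples",
                   length(y), nrow(X)))
    }
  }
  new("MatrixSource", X = X, n = nrow(X), p = ncol(X),
      variableIds = ids, response = y)
}

#' Coerce to a variable source
#'
#' @param x a [VariableSource-class], matrix or data frame.
#' @param y optional response (only when `x` is a matrix).
#' @return a [VariableSource-class].
#' @export
asVariableSource <- function(x, y = NULL) {
  if (is(x, "VariableSource")) {
    if (!is.null(y)) stop("y must be NULL when x is already a VariableSource")
    return(x)
  }
  matrixSource(x, y)
}

#' Lazily read columns of a delimited genotype table
#'
#' Builds a file-backed [VariableSource-class] over a delimited text
#' file with one row per sample and one column per variable. Fetches
#' read only the requested columns from disk, so the resident set is
#' bounded by the block size of the consuming algorithm.
#'
#' @param path path to the delimited file (header required).
#' @param responseColumn name of the response column inside the file, or
#'   `NULL` when the response lives elsewhere.
#' @param sep field separator.
#' @return a `TSVSource`.
#' @export
tsvSource <- function(path, responseColumn = "y", sep = "\t") {
  header <- names(data.table::fread(path, sep = sep, nrows = 0L,
                                    header = TRUE))
  y <- numeric(0)
  if (!is.null(responseColumn) && responseColumn %in% header) {
    ycol <- data.table::fread(path, sep = sep, select = responseColumn,
                              header = TRUE)
    y <- as.numeric(ycol[[1L]])
    header <- setdiff(header, responseColumn)
  }
  nrows <- if (length(y)) length(y) else {
    nrow(data.table::fread(path, sep = sep, select = header[1L],
                           header = TRUE))
  }
  new("TSVSource", path = path, columns = header, sep = sep,
      n = as.integer(nrows), p = length(header),
      variableIds = header, response = y)
}

#' Wrap a source to record fetch statistics
#'
#' Used to verify streaming contracts: the wrapper counts fetches, the
#' widest single fetch (peak resident variables) and the total number of
#' variable-columns served (replays show up as multiples of `p`).
#'
#' @param inner a [VariableSource-class].
#' @return a `CountingSource`; inspect with [fetchStats()].
#' @export
countingSource <- function(inner) {
  stats <- new.env(parent = emptyenv())
  stats$nFetches <- 0L
  stats$maxWidth <- 0L
  stats$totalColumns <- 0
  new("CountingSource", inner = inner, stats = stats,
      n = inner@n, p = inner@p,
      variableIds = inner@variableIds, response = inner@response)
}

#' Fetch statistics of a counting source
#'
#' @param x a `CountingSource`.
#' @return list with `nFetches`, `maxWidth` and `totalColumns`.
#' @export
fetchStats <- function(x) {
  stopifnot(is(x, "CountingSource"))
  as.list(x@stats)
}

#' @describeIn nSamples samples of a source.
#' @export
setMethod("nSamples", "VariableSource", function(x) x@n)

#' @describeIn nSamples variables of a source.
#' @export
setMethod("nVariables", "VariableSource", function(x) x@p)

#' @describeIn nSamples identifiers of a source.
#' @export
setMethod("variableIds", "VariableSource", function(x) x@variableIds)

#' @describeIn nSamples response of a source.
#' @export
setMethod("responseVector", "VariableSource", function(x) x@response)

.checkIndices <- function(x, indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("empty variable index set")
  if (any(indices < 1L) || any(indices > x@p)) {
    stop(sprintf("variable indices must lie in 1..%d", x@p))
  }
  indices
}

#' @describeIn fetchVariables fetch from an in-memory matrix.
#' @export
setMethod("fetchVariables", "MatrixSource", function(x, indices) {
  indices <- .checkIndices(x, indices)
  x@X[, indices, drop = FALSE]
})

#' @describeIn fetchVariables fetch by reading only the requested
#'   columns from the backing file.
#' @export
setMethod("fetchVariables", "TSVSource", function(x, indices) {
  indices <- .checkIndices(x, indices)
  cols <- x@columns[indices]
  dt <- data.table::fread(x@path, sep = x@sep, select = unique(cols),
                          header = TRUE)
  m <- as.matrix(dt)
  storage.mode(m) <- "double"
  m[, cols, drop = FALSE]
})

#' @describeIn fetchVariables fetch through the wrapper, recording
#'   statistics.
#' @export
setMethod("fetchVariables", "CountingSource", function(x, indices) {
  st <- x@stats
  st$nFetches <- st$nFetches + 1L
  st$maxWidth <- max(st$maxWidth, length(indices))
  st$totalColumns <- st$totalColumns + length(indices)
  fetchVariables(x@inner, indices)
})

setMethod("show", "VariableSource", function(object) {
  cat(sprintf("%s: %d samples x %d variables, response %s\n",
              class(object), object@n, object@p,
              if (length(object@response)) "present" else "absent"))
})
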