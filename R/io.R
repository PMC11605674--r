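#' Write a genotype table with its response as delimited text
#'
#' One row per sample, one named column per variable, plus a response
#' column. The inverse of [readGenotypeTSV()].
#'
#' @param X numeric matrix, samples by variables.
#' @param y numeric response.
#' @param path output path.
#' @param responseColumn name of the response column.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeGenotypeTSV <- function(X, y, path, responseColumn = "y",
                             sep = "\t") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  dt <- data.table::as.data.table(X)
  dt[[responseColumn]] <- y
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

.freadChecked <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf(
      "malformed table '%s': header has %d fields but line %d has %d",
      path, nf[1L], bad, nf[bad]))
  }
  tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, fill = FALSE),
    error = function(e) {
      stop(sprintf("malformed table '%s': %s", path,
                   conditionMessage(e)))
    })
}

.asNumericMatrix <- function(dt, path) {
  m <- as.matrix(dt)
  if (!is.numeric(m)) {
    suppressWarnings(storage.mode(m) <- "double")
  }
  bad <- which(is.na(m))
  if (length(bad)) {
    stop(sprintf("non-numeric or missing cell in '%s' at row %d, column '%s'",
                 path, row(m)[bad[1L]], colnames(m)[col(m)[bad[1L]]]))
  }
  m
}

#' Read a delimited genotype table
#'
#' Supports two dialects. `orientation = "samples"` (default): one row
#' per sample, one column per variable, the response either as a named
#' column inside the file or in a one-column sidecar file.
#' `orientation = "variables"`: one row per variable with a leading
#' `id` column naming it, one column per sample; the response is taken
#' from the row whose id equals `responseColumn`, or from the sidecar.
#' Both dialects are normalized to samples-by-variables internally.
#'
#' @param path path to the delimited file (header required, numeric
#'   body).
#' @param orientation table layout.
#' @param responseColumn name of the response column (or row).
#' @param responseFile optional one-column file holding the response.
#' @param sep field separator.
#' @param lazy if `TRUE` (samples orientation only), return a
#'   file-backed [tsvSource()] that fetches columns on demand.
#' @return a [VariableSource-class] carrying the response.
#' @export
readGenotypeTSV <- function(path,
                            orientation = c("samples", "variables"),
                            responseColumn = "y", responseFile = NULL,
                            sep = "\t", lazy = FALSE) {
  orientation <- match.arg(orientation)
  ySide <- NULL
  if (!is.null(responseFile)) {
    ySide <- as.numeric(.freadChecked(responseFile, sep)[[1L]])
  }
  if (orientation == "samples") {
    if (lazy && is.null(ySide)) {
      return(tsvSource(path, responseColumn = responseColumn, sep = sep))
    }
    dt <- .freadChecked(path, sep)
    y <- ySide
    if (is.null(y)) {
      if (!responseColumn %in% names(dt)) {
        stop(sprintf("response column '%s' not found in '%s'",
                     responseColumn, path))
      }
      y <- as.numeric(dt[[responseColumn]])
      dt[[responseColumn]] <- NULL
    }
    X <- .asNumericMatrix(dt, path)
  } else {
    dt <- .freadChecked(path, sep)
    if (!"id" %in% names(dt)) {
      stop("variables orientation requires a leading 'id' column")
    }
    ids <- as.character(dt[["id"]])
    dt[["id"]] <- NULL
    body <- .asNumericMatrix(dt, path)
    y <- ySide
    if (is.null(y)) {
      hit <- which(ids == responseColumn)
      if (!length(hit)) {
        stop(sprintf("response row '%s' not found in '%s'",
                     responseColumn, path))
      }
      y <- as.numeric(body[hit[1L], ])
      body <- body[-hit[1L], , drop = FALSE]
      ids <- ids[-hit[1L]]
    }
    X <- t(body)
    dimnames(X) <- list(NULL, ids)
  }
  if (length(y) != nrow(X)) {
    stop(sprintf("response length %d does not match %d samples",
                 length(y), nrow(X)))
  }
  matrixSource(X, y)
}

#' Read a PLINK .raw-style genotype table
#'
#' Whitespace-delimited text with the six standard leading columns
#' (FID, IID, PAT, MAT, SEX, PHENOTYPE) followed by one 0/1/2 dosage
#' column per variant. A case/control phenotype coded \{1, 2\} is
#' recoded to \{0, 1\}; any other numeric phenotype is kept as is.
#' Missing genotypes are an error unless `imputeMean` replaces them by
#' the per-variant mean (with a warning giving the count).
#'
#' @param path path to the file.
#' @param imputeMean impute missing genotypes by the per-variant mean.
#' @return a `MatrixSource` carrying the phenotype as response.
#' @export
readPlinkRaw <- function(path, imputeMean = FALSE) {
  dt <- data.table::fread(path, header = TRUE)
  if (ncol(dt) < 7L) {
    stop("expected 6 leading columns (FID IID PAT MAT SEX PHENOTYPE) plus genotypes")
  }
  pheno <- as.numeric(dt[[6L]])
  if (all(pheno %in% c(1, 2))) pheno <- pheno - 1
  G <- as.matrix(dt[, -(1:6), drop = FALSE])
  suppressWarnings(storage.mode(G) <- "double")
  nas <- is.na(G)
  if (any(nas)) {
    if (!imputeMean) {
      badVar <- colnames(G)[which(colSums(nas) > 0)[1L]]
      stop(sprintf("missing genotypes (first in variant '%s'); rerun with imputeMean = TRUE to impute per-variant means",
                   badVar))
    }
    means <- colMeans(G, na.rm = TRUE)
    G[nas] <- means[col(G)[nas]]
    warning(sprintf("imputed %d missing genotypes by per-variant means",
                    sum(nas)))
  }
  matrixSource(G, pheno)
}

#' Read dosages from a minimal biallelic VCF
#'
#' Extracts GT fields as alternate-allele counts \{0, 1, 2\} (phased or
#' unphased). Multiallelic sites and sites with any missing GT are
#' skipped with a message giving the count. Variable identifiers are
#' `CHROM:POS:REF:ALT`. VCFs carry no phenotype, so the returned source
#' has an empty response.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return a `MatrixSource` (samples by variants) with empty response.
#' @export
readVCFDosage <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  missing <- is.na(gt) | a1 == "." | a2 == "."
  drop <- multi | rowSums(missing) > 0
  if (any(drop)) {
    message(sprintf("skipped %d multiallelic or incomplete sites",
                    sum(drop)))
  }
  keep <- !drop
  dose <- (a1 == "1") + (a2 == "1")
  dose <- matrix(as.numeric(dose), nrow = nrow(gt))
  X <- t(dose[keep, , drop = FALSE])
  colnames(X) <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
                       fix[keep, "REF"], fix[keep, "ALT"], sep = ":")
  rownames(X) <- colnames(gt)
  matrixSource(X)
}

.scoreTableColumns <- c("variable_id", "score", "rank", "method",
                        "coverage")

#' Write scores as a ranked TSV table
#'
#' Columns: `variable_id`, `score` (full precision, round-trips to
#' within 1 ulp), `rank` (permutation of 1..p under the declared
#' ranking mode, ties broken by variable index), `method`, `coverage`.
#'
#' @param x a [CLSResult], or a numeric score vector.
#' @param path output path.
#' @param mode ranking mode used for the `rank` column.
#' @return `path`, invisibly.
#' @export
writeScores <- function(x, path, mode = c("absolute", "largest")) {
  mode <- match.arg(mode)
  if (is(x, "CLSResult")) {
    sc <- x@scores
    ids <- x@variableIds
    method <- x@method
    cov <- x@coverage
  } else {
    sc <- as.numeric(x)
    ids <- if (!is.null(names(x))) names(x) else
      paste0("V", seq_along(sc))
    method <- "scores"
    cov <- rep(1L, length(sc))
  }
  key <- if (mode == "absolute") abs(sc) else sc
  ord <- order(-key, seq_along(sc))
  rk <- integer(length(sc))
  rk[ord] <- seq_along(sc)
  df <- data.frame(variable_id = ids,
                   score = sprintf("%.17g", sc),
                   rank = rk,
                   method = method,
                   coverage = cov,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [writeScores()]
#'
#' @param path path to the TSV.
#' @return data frame with columns `variable_id`, `score`, `rank`,
#'   `method`, `coverage`.
#' @export
readScores <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!identical(names(dt), .scoreTableColumns)) {
    stop(sprintf("malformed score table header: expected %s",
                 paste(.scoreTableColumns, collapse = ", ")))
  }
  out <- as.data.frame(dt)
  out$variable_id <- as.character(out$variable_id)
  out$score <- as.numeric(out$score)
  out$rank <- as.integer(out$rank)
  out$coverage <- as.integer(out$coverage)
  out
}

#' Write a simulated dataset as genotype TSV plus truth sidecar
#'
#' @param ds a [SimulatedDataset].
#' @param prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.truth.json`.
#' @return character vector of the two paths, invisibly.
#' @export
writeDataset <- function(ds, prefix) {
  stopifnot(is(ds, "SimulatedDataset"))
  dataPath <- paste0(prefix, ".tsv")
  truthPath <- paste0(prefix, ".truth.json")
  writeGenotypeTSV(ds@X, ds@y, dataPath)
  terms <- lapply(ds@model@terms, function(tm) {
    list(vars = tm$vars, coef = tm$coef, negated = tm$negated)
  })
  jsonlite::write_json(
    list(truth = ds@truth,
         beta0 = ds@model@beta0,
         terms = terms,
         seed = ds@seed),
    truthPath, auto_unbox = TRUE, digits = NA, na = "string")
  invisible(c(dataPath, truthPath))
}
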