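#' Construct a Boolean SNP interaction term
#'
#' A term is a conjunction of dominant SNP indicators: the literal for
#' variable j is true iff its genotype is at least 1 (the SNP is
#' present), inverted when `negated`.
#'
#' @param vars integer variable indices.
#' @param coef numeric coefficient \eqn{\beta_j} of the term.
#' @param negated logical, recycled to the length of `vars`.
#' @return a list usable inside [interactionModel()].
#' @export
snpTerm <- function(vars, coef, negated = FALSE) {
  vars <- as.integer(vars)
  negated <- rep_len(as.logical(negated), length(vars))
  list(vars = vars, coef = as.numeric(coef), negated = negated)
}

#' Construct an interaction model
#'
#' @param beta0 numeric intercept of the logistic model.
#' @param terms list of terms built with [snpTerm()].
#' @return an [InteractionModel].
#' @export
interactionModel <- function(beta0, terms = list()) {
  new("InteractionModel", beta0 = as.numeric(beta0), terms = terms)
}

#' @describeIn truthVariables truth of a model.
#' @export
setMethod("truthVariables", "InteractionModel", function(x) {
  active <- Filter(function(tm) tm$coef != 0, x@terms)
  sort(unique(unlist(lapply(active, `[[`, "vars"), use.names = FALSE)))
})

#' @describeIn truthVariables truth of a simulated dataset.
#' @export
setMethod("truthVariables", "SimulatedDataset", function(x) x@truth)

setMethod("show", "InteractionModel", function(object) {
  cat(sprintf("InteractionModel: beta0 = %.4g, %d term(s)\n",
              object@beta0, length(object@terms)))
  for (tm in object@terms) {
    lits <- ifelse(tm$negated, paste0("!SNP", tm$vars),
                   paste0("SNP", tm$vars))
    cat(sprintf("  %s * (%s)\n", format(tm$coef, digits = 4),
                paste(lits, collapse = " & ")))
  }
})

setMethod("show", "SimulatedDataset", function(object) {
  cat(sprintf("SimulatedDataset: n = %d, p = %d, truth = {%s}\n",
              nrow(object@X), ncol(object@X),
              paste(object@truth, collapse = ", ")))
})

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws a minor allele frequency \eqn{m_j \sim U(mafLow, mafHigh)}
#' independently for every SNP, then genotypes \eqn{g_{ij} \in \{0, 1,
#' 2\}} with HWE probabilities \eqn{((1-m)^2, 2m(1-m), m^2)},
#' independently across samples and SNPs.
#'
#' @param n number of samples.
#' @param p number of SNPs.
#' @param mafLow,mafHigh bounds of the MAF distribution; must satisfy
#'   `0 < mafLow <= mafHigh < 0.5`.
#' @param seed optional RNG seed.
#' @return list with components `X` (n x p matrix, columns named
#'   `SNP1..SNPp`) and `mafs`.
#' @export
simulateGenotypes <- function(n, p, mafLow = 0.15, mafHigh = 0.45,
                              seed = NULL) {
  if (mafLow <= 0 || mafHigh >= 0.5 || mafLow > mafHigh) {
    stop("need 0 < mafLow <= mafHigh < 0.5 (a minor allele frequency)")
  }
  if (!is.null(seed)) set.seed(seed)
  mafs <- stats::runif(p, mafLow, mafHigh)
  X <- matrix(stats::rbinom(n * p, 2L, rep(mafs, each = n)), n, p)
  storage.mode(X) <- "double"
  colnames(X) <- paste0("SNP", seq_len(p))
  list(X = X, mafs = mafs)
}

#' Evaluate a Boolean interaction term on a genotype matrix
#'
#' Dominant coding: a literal is true iff the genotype is at least 1
#' (at least one variant allele present), inverted for negated
#' literals; the term is the conjunction of its literals.
#'
#' @param X genotype matrix, samples by variables.
#' @param term a term built with [snpTerm()].
#' @return integer 0/1 vector of length `nrow(X)`.
#' @export
evaluateTerm <- function(X, term) {
  if (any(term$vars > ncol(X))) stop("term indices exceed p")
  ind <- X[, term$vars, drop = FALSE] >= 1
  ind[, term$negated] <- !ind[, term$negated, drop = FALSE]
  as.integer(rowSums(ind) == length(term$vars))
}

#' Simulate a binary response from a logistic interaction model
#'
#' Draws \eqn{y_i \sim \mathrm{Bernoulli}(\pi_i)} with
#' \eqn{\pi_i = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j
#' M_j(x_i))}, where the \eqn{M_j} are the Boolean terms of the model.
#'
#' @param X genotype matrix.
#' @param model an [InteractionModel].
#' @param seed optional RNG seed.
#' @return numeric 0/1 vector of length `nrow(X)`.
#' @export
simulateResponse <- function(X, model, seed = NULL) {
  stopifnot(is(model, "InteractionModel"))
  if (!is.null(seed)) set.seed(seed)
  lp <- rep(model@beta0, nrow(X))
  for (tm in model@terms) {
    lp <- lp + tm$coef * evaluateTerm(X, tm)
  }
  as.numeric(stats::rbinom(nrow(X), 1L, stats::plogis(lp)))
}

.scenarioModels <- function(name) {
  b0 <- log(0.3 / 0.7)
  b1 <- log(50)
  weak <- log(1.1)
  switch(name,
    s1 = interactionModel(b0, list(snpTerm(1:2, b1))),
    s2 = interactionModel(b0, list(snpTerm(1:2, b1), snpTerm(3:4, b1))),
    negative = interactionModel(b0, list(snpTerm(1:2, b1,
                                                 negated = TRUE))),
    weak_main = interactionModel(b0, list(snpTerm(1L, weak),
                                          snpTerm(2L, weak))),
    weak_main_plus_interaction = interactionModel(
      b0, list(snpTerm(1L, weak), snpTerm(2L, weak), snpTerm(1:2, b1))),
    stop(sprintf(
      "unknown scenario '%s'; valid: s1, s2, negative, weak_main, weak_main_plus_interaction",
      name)))
}

#' Simulate a preset SNP scenario
#'
#' Generates genotypes under HWE with MAF ~ U(mafLow, mafHigh) and a
#' binary response from a logistic model with intercept
#' `log(0.3/0.7)` (baseline disease probability 0.3). Presets:
#' \describe{
#'   \item{`s1`}{one interaction SNP1 & SNP2 with coefficient log(50);
#'     the disease probability is 0.3 without the pattern and about
#'     0.955 with it. Truth \{1, 2\}.}
#'   \item{`s2`}{two interactions (SNP1 & SNP2) and (SNP3 & SNP4), both
#'     with coefficient log(50). Truth \{1, 2, 3, 4\}.}
#'   \item{`negative`}{the *absence* of the SNP1 & SNP2 pattern favors
#'     disease: a log(50) coefficient on the conjunction of the negated
#'     dominant indicators. The important variables then attain largely
#'     negative cross leverage scores.}
#'   \item{`weak_main`}{two single-SNP terms with coefficient log(1.1),
#'     marginal effects too small to matter.}
#'   \item{`weak_main_plus_interaction`}{the same plus a log(50)
#'     interaction of SNP1 & SNP2.}
#' }
#'
#' @param name scenario name.
#' @param n number of samples (study default 120).
#' @param p number of SNPs; must cover the scenario's SNPs.
#' @param seed optional RNG seed (genotypes and response).
#' @param mafLow,mafHigh MAF bounds.
#' @return a [SimulatedDataset].
#' @export
simulateScenario <- function(name = c("s1", "s2", "negative", "weak_main",
                                      "weak_main_plus_interaction"),
                             n = 120, p = 2000, seed = NULL,
                             mafLow = 0.15, mafHigh = 0.45) {
  name <- match.arg(name)
  model <- .scenarioModels(name)
  truth <- truthVariables(model)
  if (p < max(truth)) {
    stop(sprintf("scenario '%s' needs p >= %d", name, max(truth)))
  }
  if (!is.null(seed)) set.seed(seed)
  g <- simulateGenotypes(n, p, mafLow, mafHigh, seed = NULL)
  y <- simulateResponse(g$X, model, seed = NULL)
  new("SimulatedDataset",
      X = g$X,
      y = y,
      mafs = g$mafs,
      truth = truth,
      model = model,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
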