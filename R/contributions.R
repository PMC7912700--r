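#' Kullback-Leibler contribution of the common factors
#'
#' The entropy-based (symmetrized Kullback-Leibler) contribution of the
#' common-factor vector to the manifest variables is a signal-to-noise
#' ratio: each standardized variable contributes its explained variance
#' (communality) divided by its unique variance,
#' \deqn{KL(X, \xi) = \sum_i \frac{(\Lambda \Phi \Lambda^T)_{ii}}{\omega_i^2},}
#' and the total over any subset of variables is the sum of the per-variable
#' terms (additivity over variables and over any partition into subvectors).
#'
#' @param model a \linkS4class{FactorModel}.
#' @param subset optional variable indices or names; the full vector when
#'   omitted.
#' @return nonnegative scalar KL contribution.
#' @examples
#' m1 <- exampleModel("example1")
#' klContribution(m1)                 # 9.744
#' klContribution(m1, c("X4", "X5"))  # 6.330
#' @export
klContribution <- function(model, subset = NULL) {
  stopifnot(is(model, "FactorModel"))
  idx <- .resolveSubset(model, subset)
  sum(variableContributions(model)[idx])
}

#' Per-variable Kullback-Leibler contributions
#'
#' Entry i is \eqn{KL(X_i, \xi) = (\Lambda \Phi \Lambda^T)_{ii} /
#' \omega_i^2}, the explained-to-unique variance ratio of variable i.  The
#' entries sum to \code{\link{klContribution}(model)}.
#'
#' @param model a \linkS4class{FactorModel}.
#' @return named length-p numeric vector.
#' @export
variableContributions <- function(model) {
  stopifnot(is(model, "FactorModel"))
  h2 <- rowSums((model@loadings %*% model@factorCorr) * model@loadings)
  out <- h2 / model@uniqueVars
  names(out) <- rownames(model@loadings)
  out
}

#' Contribution of a single (derived) factor
#'
#' For a factor \eqn{\eta = f^T \xi} given by a nonzero coefficient vector
#' f, the contribution to the manifest vector is
#' \deqn{C(\eta \to X) = \sum_i \frac{Cov(X_i, \eta)^2}{\omega_i^2\,
#'   Var(\eta)}, \qquad Cov(X, \eta) = \Lambda \Phi f,\ Var(\eta) = f^T \Phi f.}
#' This marginal form equals the conditional-information definition
#' \eqn{KL(X, \xi) - KL(X, \xi_{\setminus}|\eta)} under the Gaussian joint
#' distribution of (X, xi): conditioning on \eqn{\eta} reduces
#' \eqn{Cov(X_i, \theta_i)} by exactly \eqn{Cov(X_i, \eta)^2 / Var(\eta)}.
#' The value is invariant to rescaling of f.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param coefs length-m nonzero numeric vector f.
#' @param subset optional variable indices or names restricting the target
#'   manifest vector.
#' @return nonnegative scalar contribution.
#' @examples
#' m2 <- exampleModel("example2")
#' g <- loadingMatrix(m2)["X1", ]   # Spearman-g direction
#' factorContribution(m2, g)        # 19.93
#' @export
factorContribution <- function(model, coefs, subset = NULL) {
  stopifnot(is(model, "FactorModel"))
  f <- as.numeric(coefs)
  m <- ncol(model@loadings)
  if (length(f) != m)
    stop(sprintf("'coefs' must have length %d", m))
  vEta <- drop(t(f) %*% model@factorCorr %*% f)
  if (!(vEta > 0))
    stop("'coefs' must be a nonzero coefficient vector")
  idx <- .resolveSubset(model, subset)
  cv <- drop(model@loadings[idx, , drop = FALSE] %*% model@factorCorr %*% f)
  sum(cv^2 / model@uniqueVars[idx]) / vEta
}

# Conditional KL(X, . | eta) by explicit Gaussian conditioning of the joint
# covariance of (X, xi) on eta = f' xi.  Used as an independent oracle for
# factorContribution; exported for transparency.

#' Conditional KL contribution given a single factor
#'
#' Computes \eqn{KL(X, \xi_{\setminus} | \eta)} for \eqn{\eta = f^T \xi} by
#' conditioning the Gaussian joint covariance of (X, xi) on eta and summing
#' the conditional \eqn{Cov(X_i, \theta_i | \eta) / \omega_i^2}.  Serves as
#' the conditional-information route to single-factor contributions:
#' \code{klContribution(model) - conditionalKL(model, f)} equals
#' \code{factorContribution(model, f)}.
#'
#' @inheritParams factorContribution
#' @return nonnegative scalar.
#' @export
conditionalKL <- function(model, coefs) {
  stopifnot(is(model, "FactorModel"))
  f <- as.numeric(coefs)
  Phi <- model@factorCorr
  L <- model@loadings
  vEta <- drop(t(f) %*% Phi %*% f)
  if (!(vEta > 0)) stop("'coefs' must be a nonzero coefficient vector")
  covXeta <- drop(L %*% Phi %*% f)     # Cov(X, eta)
  covXiEta <- drop(Phi %*% f)          # Cov(xi, eta)
  # Cov(X, xi | eta) = Lambda Phi - Cov(X,eta) Cov(xi,eta)' / Var(eta)
  crossCond <- L %*% Phi - tcrossprod(covXeta, covXiEta) / vEta
  # Cov(X_i, theta_i | eta) = row_i(crossCond) . lambda_i
  condCov <- rowSums(crossCond * L)
  sum(condCov / model@uniqueVars)
}

#' Assemble an entropy contribution report
#'
#' Computes the total KL contribution, its per-variable decomposition, the
#' per-group decomposition for a given grouping of the manifest variables,
#' single-factor contributions for a set of factor coefficient vectors
#' (defaulting to the m coordinate factors), the entropy coefficient of
#' determination ECD = KL/(KL+1), and the relative contributions
#' RC = C/KL and RCtilde = C/(KL+1).  For correlated factors the RC values
#' need not sum to one and can exceed it in total; they are reported as is.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param groups optional named list of variable index/name sets.
#' @param factorSet optional named list of length-m coefficient vectors; the
#'   m coordinate factors when omitted.
#' @return a \linkS4class{ContributionReport}.
#' @examples
#' rep1 <- contributionReport(exampleModel("example1"))
#' rep1@ecd   # 0.907
#' @export
contributionReport <- function(model, groups = NULL, factorSet = NULL) {
  stopifnot(is(model, "FactorModel"))
  perVar <- variableContributions(model)
  total <- sum(perVar)
  perGroup <- numeric(0)
  if (!is.null(groups)) {
    gidx <- .resolveGroups(model, groups)
    perGroup <- vapply(gidx, function(i) sum(perVar[i]), numeric(1))
  }
  m <- ncol(model@loadings)
  if (is.null(factorSet)) {
    factorSet <- lapply(seq_len(m), function(j) { e <- numeric(m); e[j] <- 1; e })
    names(factorSet) <- colnames(model@loadings)
  }
  if (is.null(names(factorSet)) || any(!nzchar(names(factorSet))))
    names(factorSet) <- paste0("eta", seq_along(factorSet))
  perFactor <- vapply(factorSet, function(f) factorContribution(model, f),
                      numeric(1))
  new("ContributionReport",
      totalKL = total,
      perVariable = perVar,
      perGroup = perGroup,
      perFactor = perFactor,
      ecd = total / (total + 1),
      rc = perFactor / total,
      rcTilde = perFactor / (total + 1))
}

setMethod("show", "ContributionReport", function(object) {
  cat("Entropy contribution report\n")
  cat(sprintf("  total KL contribution: %.3f   ECD: %.3f\n",
              object@totalKL, object@ecd))
  cat("  per variable:\n")
  print(round(object@perVariable, 3))
  if (length(object@perGroup)) {
    cat("  per group:\n")
    print(round(object@perGroup, 3))
  }
  cat("  per factor (C, RC, RCtilde):\n")
  print(round(cbind(C = object@perFactor, RC = object@rc,
                    RCtilde = object@rcTilde), 3))
  invisible(object)
})

#' @rdname ContributionReport-class
#' @param x a \code{ContributionReport}.
#' @export
setMethod("totalKL", "ContributionReport", function(x) x@totalKL)
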