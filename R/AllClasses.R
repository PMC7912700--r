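#' @import methods
NULL

#' Fitted factor-analysis model
#'
#' An S4 container for a fitted common-factor model for p standardized
#' manifest variables and m common factors:
#' \deqn{X_i = \sum_{j=1}^m \lambda_{ij} \xi_j + \epsilon_i,}
#' with unit-variance factors, \eqn{Cov(\xi_k, \xi_l) = \phi_{kl}},
#' uncorrelated unique factors and \eqn{Var(\epsilon_i) = \omega_i^2 > 0}.
#' The model-implied manifest covariance is
#' \eqn{\Sigma = \Lambda \Phi \Lambda^T + \Omega} with
#' \eqn{\Omega = diag(\omega^2)}.
#'
#' The object is the single source of truth for every contribution and
#' canonical quantity in the package: no raw data are stored, only the
#' population parameters of the fitted model.
#'
#' @slot loadings p x m numeric matrix of factor loadings (Lambda), with
#'   variable names as rownames and factor names as colnames.
#' @slot factorCorr m x m factor covariance matrix (Phi); a correlation
#'   matrix (unit diagonal) when \code{standardizedFactors} is \code{TRUE}.
#' @slot uniqueVars length-p positive numeric of unique variances (omega^2).
#' @slot standardizedFactors logical; \code{FALSE} for models produced by
#'   \code{\link{transformModel}} with a non-orthonormal transform, whose
#'   factor covariance may have non-unit diagonal.
#'
#' @seealso \code{\link{factorModel}}, \code{\link{impliedCovariance}},
#'   \code{\link{klContribution}}, \code{\link{canonicalDecomposition}}
#' @export
setClass("FactorModel",
  representation(
    loadings = "matrix",
    factorCorr = "matrix",
    uniqueVars = "numeric",
    standardizedFactors = "logical"
  )
)

setValidity("FactorModel", function(object) {
  L <- object@loadings
  Phi <- object@factorCorr
  w <- object@uniqueVars
  msg <- character()
  if (!is.numeric(L) || nrow(L) < 1L || ncol(L) < 1L)
    msg <- c(msg, "'loadings' must be a numeric matrix with p >= 1, m >= 1")
  if (anyNA(L) || anyNA(Phi) || anyNA(w))
    msg <- c(msg, "model parameters must not contain NA")
  if (nrow(Phi) != ncol(L) || ncol(Phi) != ncol(L))
    msg <- c(msg, sprintf("'factorCorr' must be %d x %d", ncol(L), ncol(L)))
  if (length(w) != nrow(L))
    msg <- c(msg, sprintf("'uniqueVars' must have length %d", nrow(L)))
  if (length(msg)) return(msg)
  if (max(abs(Phi - t(Phi))) > 1e-8)
    msg <- c(msg, "'factorCorr' must be symmetric")
  if (object@standardizedFactors && max(abs(diag(Phi) - 1)) > 1e-8)
    msg <- c(msg, "'factorCorr' must have unit diagonal for standardized factors")
  if (!.isPositiveDefinite(Phi))
    msg <- c(msg, "'factorCorr' must be positive definite")
  if (any(w <= 0))
    msg <- c(msg, sprintf("all unique variances must be > 0 (violated by %s)",
                          paste(rownames(L)[w <= 0], collapse = ", ")))
  if (!length(msg)) {
    Sigma <- L %*% Phi %*% t(L) + diag(w, nrow(L))
    if (!.isPositiveDefinite(Sigma))
      msg <- c(msg, "implied covariance Lambda Phi Lambda' + diag(omega^2) is not positive definite")
  }
  if (length(msg)) msg else TRUE
})

#' Joint covariance of manifest variables and common factors
#'
#' The block covariance matrix of the stacked vector (X, xi):
#' manifest block \eqn{\Sigma = \Lambda \Phi \Lambda^T + \Omega},
#' cross block \eqn{\Lambda \Phi = Cov(X, \xi)} and factor block \eqn{\Phi}.
#'
#' @slot manifestBlock p x p matrix (Sigma).
#' @slot crossBlock p x m matrix (Lambda Phi).
#' @slot factorBlock m x m matrix (Phi).
#' @seealso \code{\link{impliedCovariance}}
#' @export
setClass("JointCovariance",
  representation(
    manifestBlock = "matrix",
    crossBlock = "matrix",
    factorBlock = "matrix"
  )
)

setValidity("JointCovariance", function(object) {
  p <- nrow(object@manifestBlock)
  if (nrow(object@crossBlock) != p ||
      ncol(object@crossBlock) != nrow(object@factorBlock))
    return("block dimensions are inconsistent")
  full <- rbind(cbind(object@manifestBlock, object@crossBlock),
                cbind(t(object@crossBlock), object@factorBlock))
  if (!.isPositiveDefinite(full))
    return("assembled (p+m) x (p+m) covariance is not positive definite")
  TRUE
})

#' Canonical decomposition of a factor contribution
#'
#' Ordered canonical pairs between a (sub)vector of manifest variables and
#' the common-factor vector, computed from model-implied covariances.  Pair
#' j carries the squared canonical correlation \eqn{\rho_j^2}, the
#' factor-side coefficients (column j of \code{factorCoefs}; the canonical
#' common factor is \eqn{\eta_j = f_j^T \xi}), the manifest-side
#' coefficients (\eqn{V_j = b_j^T X}), and the entropy contribution
#' \eqn{\rho_j^2 / (1 - \rho_j^2)}.  Contributions sum to the
#' Kullback-Leibler contribution of the analyzed subvector.
#'
#' @slot subset integer indices of the analyzed manifest variables.
#' @slot rhoSq squared canonical correlations, descending.
#' @slot contributions per-pair contributions rho^2/(1-rho^2).
#' @slot factorCoefs m x k matrix; column j is f_j, normalized to unit
#'   variance under Phi.
#' @slot manifestCoefs |subset| x k matrix; column j is b_j, normalized to
#'   unit variance under the subset's implied covariance.
#' @slot totalKL sum of contributions (= KL contribution of the subset).
#' @slot rc relative contributions, contribution / totalKL of the subset.
#' @slot rcTilde contributions / (totalKL + 1).
#' @slot capped logical per pair; TRUE where rho^2 was within tolerance of 1
#'   and the contribution was capped.
#' @seealso \code{\link{canonicalDecomposition}}, \code{\link{subgroupAnalysis}}
#' @export
setClass("CanonicalDecomposition",
  representation(
    subset = "integer",
    rhoSq = "numeric",
    contributions = "numeric",
    factorCoefs = "matrix",
    manifestCoefs = "matrix",
    totalKL = "numeric",
    rc = "numeric",
    rcTilde = "numeric",
    capped = "logical"
  )
)

#' Factor model re-expressed in derived (generally oblique) factors
#'
#' Holds a full-rank re-parametrization eta = G xi of the common-factor
#' space: the coefficient matrix G (rows scaled to unit variance under Phi),
#' the re-expressed loadings \eqn{\Lambda^* = \Lambda G^{-1}}, the derived
#' factor covariance \eqn{G \Phi G^T} (off-diagonal entries are the
#' correlations between the derived factors), and the entropy contribution
#' of each derived factor to the full manifest vector.  Uniquenesses are
#' unchanged by re-parametrization, and the implied manifest covariance is
#' preserved exactly.
#'
#' @slot coefMatrix m x m matrix G with rows g_k (eta_k = g_k' xi).
#' @slot newLoadings p x m matrix Lambda* = Lambda G^-1.
#' @slot factorCorrNew m x m matrix G Phi G', unit diagonal.
#' @slot contributionsFull length-m contributions C(eta_k -> X).
#' @slot contributionsGroups named list (possibly empty): per-group
#'   contribution and relative contribution of each derived factor.
#' @slot uniqueVars length-p unique variances (copied from the model).
#' @seealso \code{\link{deriveFactorSystem}}, \code{\link{selectLeadingFactors}}
#' @export
setClass("DerivedFactorSystem",
  representation(
    coefMatrix = "matrix",
    newLoadings = "matrix",
    factorCorrNew = "matrix",
    contributionsFull = "numeric",
    contributionsGroups = "list",
    uniqueVars = "numeric"
  )
)

#' Entropy contribution report
#'
#' Assembles the Kullback-Leibler signal-to-noise contribution of the
#' common-factor vector to the manifest vector and its decompositions:
#' per manifest variable, per variable group, and per (possibly derived)
#' factor; plus the entropy coefficient of determination
#' ECD = KL/(KL + 1) and the relative contributions RC = C/KL and
#' RCtilde = C/(KL + 1).
#'
#' @slot totalKL total contribution KL(X, xi).
#' @slot perVariable named length-p vector KL(X_i, xi).
#' @slot perGroup named numeric (empty when no groups were given).
#' @slot perFactor named numeric of single-factor contributions.
#' @slot ecd entropy coefficient of determination, in [0, 1).
#' @slot rc named numeric, perFactor / totalKL.
#' @slot rcTilde named numeric, perFactor / (totalKL + 1).
#' @seealso \code{\link{contributionReport}}
#' @export
setClass("ContributionReport",
  representation(
    totalKL = "numeric",
    perVariable = "numeric",
    perGroup = "numeric",
    perFactor = "numeric",
    ecd = "numeric",
    rc = "numeric",
    rcTilde = "numeric"
  )
)
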