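#' Leading canonical factor of each variable group
#'
#' For m groups of manifest variables, extracts the factor-side coefficient
#' vector of each group's leading canonical pair and stacks them into an
#' m x m coefficient matrix G (rows \eqn{g_a}, derived factors
#' \eqn{\eta_a = g_a^T \xi}).  This is the substantive route to
#' interpretable factors: each derived factor is the direction in the
#' common-factor space most correlated with a conceptually meaningful group
#' of variables (e.g. liberal-arts versus science scores).
#'
#' @param model a \linkS4class{FactorModel}.
#' @param groups named list of exactly m variable sets, in the desired
#'   factor order.
#' @return m x m matrix G with one unit-variance row per group.
#' @examples
#' m1 <- exampleModel("example1")
#' selectLeadingFactors(m1, list(arts = c("X1","X2","X3"),
#'                               science = c("X4","X5")))
#' @export
selectLeadingFactors <- function(model, groups) {
  stopifnot(is(model, "FactorModel"))
  gidx <- .resolveGroups(model, groups)
  m <- ncol(model@loadings)
  if (length(gidx) != m)
    stop(sprintf(paste0("need exactly m = %d groups to span the factor space ",
                        "(got %d): a square coefficient matrix is required ",
                        "for re-expressed loadings"), m, length(gidx)))
  G <- t(vapply(gidx,
                function(i) canonicalDecomposition(model, i)@factorCoefs[, 1L],
                numeric(m)))
  dimnames(G) <- list(names(gidx), colnames(model@loadings))
  if (!is.finite(kappa(G, exact = TRUE)) || kappa(G, exact = TRUE) > .condCap)
    stop("leading group factors are (numerically) linearly dependent; ",
         "choose a different grouping")
  G
}

#' Re-express the model in derived oblique factors
#'
#' Given a nonsingular m x m coefficient matrix G (rows defining derived
#' factors \eqn{\eta_k = g_k^T \xi}; rows are rescaled to unit variance
#' under \eqn{\Phi}), computes the re-expressed loading matrix
#' \eqn{\Lambda^* = \Lambda G^{-1}}, the derived-factor correlation matrix
#' \eqn{G \Phi G^T}, and the entropy contribution of each derived factor to
#' the full manifest vector.  The re-parametrization is exact:
#' \eqn{\Lambda^* G = \Lambda} and the implied manifest covariance is
#' unchanged, so the total KL contribution is preserved.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param coefMatrix m x m coefficient matrix G; when \code{NULL} it is
#'   built from \code{groups} via \code{\link{selectLeadingFactors}}.
#' @param groups optional named list of variable sets; with
#'   \code{coefMatrix = NULL} these define the derived factors, and in all
#'   cases per-group contributions of each derived factor are reported.
#' @return a \linkS4class{DerivedFactorSystem}.
#' @examples
#' m1 <- exampleModel("example1")
#' sys <- deriveFactorSystem(m1, groups = list(arts = c("X1","X2","X3"),
#'                                             science = c("X4","X5")))
#' round(newLoadings(sys), 2)          # oblique-loading table
#' factorCorrNew(sys)["arts","science"]  # 0.375
#' @export
deriveFactorSystem <- function(model, coefMatrix = NULL, groups = NULL) {
  stopifnot(is(model, "FactorModel"))
  m <- ncol(model@loadings)
  Phi <- model@factorCorr
  if (is.null(coefMatrix)) {
    if (is.null(groups))
      stop("supply 'coefMatrix' or 'groups'")
    G <- selectLeadingFactors(model, groups)
  } else {
    G <- as.matrix(coefMatrix)
    if (nrow(G) != m || ncol(G) != m)
      stop(sprintf(paste0("'coefMatrix' must be %d x %d; contributions of ",
                          "fewer than m factors are available via ",
                          "factorContribution(), but re-expressed loadings ",
                          "require a full-rank square system"), m, m))
    if (is.null(rownames(G))) rownames(G) <- paste0("eta", seq_len(m))
    colnames(G) <- colnames(model@loadings)
  }
  # rescale rows to unit variance under Phi
  sdv <- sqrt(diag(G %*% Phi %*% t(G)))
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("'coefMatrix' has a zero row; derived factors must be nonzero")
  G <- G / sdv
  .assertSquareNonsingular(G, "coefMatrix")

  Ginv <- solve(G)
  Lstar <- model@loadings %*% Ginv
  PhiNew <- G %*% Phi %*% t(G)
  PhiNew <- (PhiNew + t(PhiNew)) / 2
  dimnames(Lstar) <- list(rownames(model@loadings), rownames(G))
  dimnames(PhiNew) <- list(rownames(G), rownames(G))

  contribFull <- vapply(seq_len(m),
                        function(k) factorContribution(model, G[k, ]),
                        numeric(1))
  names(contribFull) <- rownames(G)

  contribGroups <- list()
  if (!is.null(groups)) {
    gidx <- .resolveGroups(model, groups)
    perVar <- variableContributions(model)
    contribGroups <- lapply(gidx, function(i) {
      Ck <- vapply(seq_len(m),
                   function(k) factorContribution(model, G[k, ], subset = i),
                   numeric(1))
      names(Ck) <- rownames(G)
      list(contributions = Ck, rc = Ck / sum(perVar[i]))
    })
  }

  new("DerivedFactorSystem",
      coefMatrix = G,
      newLoadings = Lstar,
      factorCorrNew = PhiNew,
      contributionsFull = contribFull,
      contributionsGroups = contribGroups,
      uniqueVars = model@uniqueVars)
}

#' @rdname DerivedFactorSystem-class
#' @param x a \code{DerivedFactorSystem}.
#' @export
setMethod("coefMatrix", "DerivedFactorSystem", function(x) x@coefMatrix)

#' @rdname DerivedFactorSystem-class
#' @export
setMethod("newLoadings", "DerivedFactorSystem", function(x) x@newLoadings)

#' @rdname DerivedFactorSystem-class
#' @export
setMethod("factorCorrNew", "DerivedFactorSystem", function(x) x@factorCorrNew)

#' @rdname DerivedFactorSystem-class
#' @export
setMethod("contributions", "DerivedFactorSystem", function(x) x@contributionsFull)

setMethod("show", "DerivedFactorSystem", function(object) {
  cat("Derived (oblique) factor system\n")
  cat("Loadings on derived factors:\n")
  print(round(object@newLoadings, 3))
  cat("Derived factor correlations:\n")
  print(round(object@factorCorrNew, 3))
  cat("Contributions to the full manifest vector:\n")
  print(round(object@contributionsFull, 3))
  invisible(object)
})

#' Convert a derived factor system back to a FactorModel
#'
#' Packages the re-expressed loadings, derived-factor correlation matrix and
#' the (unchanged) uniquenesses as a \linkS4class{FactorModel}, e.g. for
#' further contribution analysis on the oblique system.
#'
#' @param system a \linkS4class{DerivedFactorSystem}.
#' @return a \linkS4class{FactorModel}.
#' @export
asFactorModel <- function(system) {
  stopifnot(is(system, "DerivedFactorSystem"))
  factorModel(system@newLoadings, system@factorCorrNew,
              uniqueVars = system@uniqueVars)
}
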