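#' Construct a fitted factor-analysis model
#'
#' Builds and validates a \linkS4class{FactorModel} from a loading matrix,
#' an optional factor correlation matrix (identity when omitted, i.e.
#' orthogonal factors) and unique variances.  For standardized manifest
#' variables the uniquenesses can be recomputed as one minus the
#' communality, \eqn{\omega_i^2 = 1 - (\Lambda \Phi \Lambda^T)_{ii}};
#' published loading tables usually print rounded uniquenesses, and
#' recomputation restores full-precision consistency with the loadings.
#'
#' @param loadings p x m numeric matrix (or coercible) of factor loadings.
#' @param factorCorr optional m x m factor correlation matrix Phi; identity
#'   if \code{NULL}.
#' @param uniqueVars optional length-p positive vector of unique variances.
#' @param recomputeUniqueness logical; if \code{TRUE}, uniquenesses are set
#'   to 1 - communality (requires all communalities < 1).  Required when
#'   \code{uniqueVars} is \code{NULL}.  If both \code{uniqueVars} and the
#'   flag are supplied, the flag wins with a warning.
#' @param variableNames,factorNames optional labels; defaults X1..Xp and
#'   f1..fm.
#' @return a validated \linkS4class{FactorModel}.
#' @examples
#' m <- exampleModel("example1")
#' uniqueVars(m)
#' @export
factorModel <- function(loadings, factorCorr = NULL, uniqueVars = NULL,
                        recomputeUniqueness = is.null(uniqueVars),
                        variableNames = NULL, factorNames = NULL) {
  L <- as.matrix(loadings)
  storage.mode(L) <- "double"
  p <- nrow(L); m <- ncol(L)
  if (p < 1L || m < 1L) stop("'loadings' must have p >= 1 rows and m >= 1 columns")
  if (is.null(variableNames))
    variableNames <- if (!is.null(rownames(L))) rownames(L) else paste0("X", seq_len(p))
  if (is.null(factorNames))
    factorNames <- if (!is.null(colnames(L))) colnames(L) else paste0("f", seq_len(m))
  if (length(variableNames) != p || length(factorNames) != m)
    stop("name lengths do not match the loading matrix dimensions")
  dimnames(L) <- list(variableNames, factorNames)

  if (is.null(factorCorr)) {
    Phi <- diag(1, m)
  } else {
    Phi <- as.matrix(factorCorr)
    storage.mode(Phi) <- "double"
    if (nrow(Phi) != m || ncol(Phi) != m)
      stop(sprintf("'factorCorr' must be %d x %d to match the loadings", m, m))
  }
  dimnames(Phi) <- list(factorNames, factorNames)

  if (is.null(uniqueVars) && !recomputeUniqueness)
    stop("supply 'uniqueVars' or set 'recomputeUniqueness = TRUE'")
  if (!is.null(uniqueVars) && recomputeUniqueness)
    warning("'uniqueVars' supplied together with 'recomputeUniqueness = TRUE'; ",
            "recomputed values take precedence")
  if (recomputeUniqueness) {
    h2 <- rowSums((L %*% Phi) * L)   # diag(Lambda Phi Lambda')
    w <- 1 - h2
    if (any(w <= 0))
      stop("degenerate model: communality >= 1 for variable(s) ",
           paste(variableNames[w <= 0], collapse = ", "),
           "; uniqueness cannot be recomputed")
  } else {
    w <- as.numeric(uniqueVars)
    if (length(w) != p) stop(sprintf("'uniqueVars' must have length %d", p))
  }
  names(w) <- variableNames

  new("FactorModel", loadings = L, factorCorr = Phi, uniqueVars = w,
      standardizedFactors = TRUE)
}

#' @rdname FactorModel-class
#' @export
setMethod("loadingMatrix", "FactorModel", function(x) x@loadings)

#' @rdname FactorModel-class
#' @export
setMethod("factorCorr", "FactorModel", function(x) x@factorCorr)

#' @rdname FactorModel-class
#' @export
setMethod("uniqueVars", "FactorModel", function(x) x@uniqueVars)

#' @rdname FactorModel-class
#' @export
setMethod("nManifest", "FactorModel", function(x) nrow(x@loadings))

#' @rdname FactorModel-class
#' @export
setMethod("nFactors", "FactorModel", function(x) ncol(x@loadings))

#' @rdname FactorModel-class
#' @export
setMethod("variableNames", "FactorModel", function(x) rownames(x@loadings))

#' @rdname FactorModel-class
#' @export
setMethod("factorNames", "FactorModel", function(x) colnames(x@loadings))

#' @rdname FactorModel-class
#' @export
setMethod("communalities", "FactorModel", function(x) {
  h2 <- rowSums((x@loadings %*% x@factorCorr) * x@loadings)
  names(h2) <- rownames(x@loadings)
  h2
})

setMethod("show", "FactorModel", function(object) {
  p <- nrow(object@loadings); m <- ncol(object@loadings)
  cat(sprintf("FactorModel: %d manifest variables, %d common factors%s\n",
              p, m,
              if (object@standardizedFactors) "" else " (transformed factor basis)"))
  cat("Loadings:\n")
  print(round(object@loadings, 3))
  if (m > 1 && max(abs(object@factorCorr[upper.tri(object@factorCorr)])) > 1e-12) {
    cat("Factor covariance:\n")
    print(round(object@factorCorr, 3))
  } else if (object@standardizedFactors) {
    cat("Orthogonal factors (Phi = I)\n")
  }
  cat("Uniquenesses:\n")
  print(round(object@uniqueVars, 4))
  invisible(object)
})

#' Model-implied joint covariance of (X, xi)
#'
#' Assembles the covariance blocks of the stacked manifest/factor vector:
#' \eqn{\Sigma = \Lambda \Phi \Lambda^T + \Omega}, \eqn{Cov(X, \xi) =
#' \Lambda \Phi} and \eqn{\Phi}.
#'
#' @param model a \linkS4class{FactorModel}.
#' @return a \linkS4class{JointCovariance}.
#' @examples
#' jc <- impliedCovariance(exampleModel("example1"))
#' manifestBlock(jc)[1, 2]   # 0.5436, printed 0.54 in the source table
#' @export
impliedCovariance <- function(model) {
  stopifnot(is(model, "FactorModel"))
  L <- model@loadings
  Phi <- model@factorCorr
  cross <- L %*% Phi
  Sigma <- cross %*% t(L) + diag(model@uniqueVars, nrow(L))
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(rownames(L), rownames(L))
  new("JointCovariance", manifestBlock = Sigma, crossBlock = cross,
      factorBlock = Phi)
}

#' @rdname JointCovariance-class
#' @export
setMethod("manifestBlock", "JointCovariance", function(x) x@manifestBlock)

#' @rdname JointCovariance-class
#' @export
setMethod("crossBlock", "JointCovariance", function(x) x@crossBlock)

#' @rdname JointCovariance-class
#' @export
setMethod("factorBlock", "JointCovariance", function(x) x@factorBlock)

#' @describeIn JointCovariance-class assemble the full (p+m) x (p+m) matrix.
#' @param ... unused.
#' @export
setMethod("as.matrix", "JointCovariance", function(x, ...) {
  rbind(cbind(x@manifestBlock, x@crossBlock),
        cbind(t(x@crossBlock), x@factorBlock))
})

setMethod("show", "JointCovariance", function(object) {
  cat(sprintf("JointCovariance: %d manifest variables, %d factors\n",
              nrow(object@manifestBlock), nrow(object@factorBlock)))
  cat("Manifest block Sigma:\n")
  print(round(object@manifestBlock, 3))
  invisible(object)
})

#' Re-express the model on linearly transformed factors
#'
#' For a nonsingular m x m matrix Q defining new factors \eqn{Q \xi}, the
#' model becomes \eqn{\Lambda Q^{-1}} with factor covariance
#' \eqn{Q \Phi Q^T}; the unique variances and the implied manifest
#' covariance are unchanged.  Canonical factor analysis is invariant under
#' any such transform, which is what makes its output independent of the
#' initial factor rotation.  The transformed factor covariance is allowed a
#' non-unit diagonal; the model is flagged accordingly.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param Q nonsingular m x m matrix.
#' @param factorNames optional names for the transformed factors.
#' @return a \linkS4class{FactorModel} on the transformed basis.
#' @export
transformModel <- function(model, Q, factorNames = NULL) {
  stopifnot(is(model, "FactorModel"))
  Q <- as.matrix(Q)
  m <- ncol(model@loadings)
  if (nrow(Q) != m || ncol(Q) != m)
    stop(sprintf("'Q' must be %d x %d", m, m))
  .assertSquareNonsingular(Q, "Q")
  Lnew <- model@loadings %*% solve(Q)
  PhiNew <- Q %*% model@factorCorr %*% t(Q)
  PhiNew <- (PhiNew + t(PhiNew)) / 2
  if (is.null(factorNames)) factorNames <- paste0("t", seq_len(m))
  dimnames(Lnew) <- list(rownames(model@loadings), factorNames)
  dimnames(PhiNew) <- list(factorNames, factorNames)
  new("FactorModel", loadings = Lnew, factorCorr = PhiNew,
      uniqueVars = model@uniqueVars,
      standardizedFactors = max(abs(diag(PhiNew) - 1)) < 1e-8)
}

# Resolve a GroupSpec (named list of index vectors or variable-name vectors)
# to named integer index sets; optionally require a partition of 1..p.
.resolveGroups <- function(model, groups, partition = FALSE) {
  if (!is.list(groups) || length(groups) == 0L)
    stop("'groups' must be a non-empty named list of variable sets")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("G", seq_along(groups))
  idx <- lapply(groups, function(g) .resolveSubset(model, g))
  all <- unlist(idx, use.names = FALSE)
  if (partition) {
    p <- nrow(model@loadings)
    if (anyDuplicated(all) || length(all) != p || !setequal(all, seq_len(p)))
      stop("groups must form a partition of all manifest variables")
  } else if (anyDuplicated(all)) {
    warning("groups overlap; contribution additivity across groups does not hold")
  }
  idx
}
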