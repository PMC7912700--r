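#' Built-in example factor models
#'
#' Two small published-style fixtures used throughout the documentation and
#' tests.  \code{"example1"} is a 5-variable, 2-factor varimax solution for
#' school scores (X1-X3 liberal-arts subjects, X4-X5 science subjects);
#' \code{"example2"} is a 6-variable, 2-factor maximum-likelihood varimax
#' solution for ability scores (X1 a Spearman-g indicator, X2-X4
#' problem-solving, X5-X6 verbal).  Both use orthogonal factors and
#' uniquenesses recomputed as 1 - communality, which restores
#' full-precision consistency with the printed loadings.
#'
#' @param name \code{"example1"} or \code{"example2"}.
#' @return a \linkS4class{FactorModel}.
#' @examples
#' exampleModel("example1")
#' @export
exampleModel <- function(name = c("example1", "example2")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("example1", "example2"))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: example1, example2")
  L <- switch(name,
    example1 = rbind(
      X1 = c(0.60, 0.39),
      X2 = c(0.75, 0.24),
      X3 = c(0.65, 0.00),
      X4 = c(0.32, 0.59),
      X5 = c(0.00, 0.92)),
    example2 = rbind(
      X1 = c(0.64,  0.37),
      X2 = c(0.34,  0.54),
      X3 = c(0.46,  0.76),
      X4 = c(0.25,  0.41),
      X5 = c(0.97, -0.12),
      X6 = c(0.82, -0.03)))
  colnames(L) <- c("f1", "f2")
  factorModel(L, recomputeUniqueness = TRUE)
}

#' Simulate a random factor model with simple structure
#'
#' Generates a valid \linkS4class{FactorModel} emulating the
#' simple-structure pattern of rotated solutions: each manifest variable
#' has one dominant loading on an assigned factor and small cross-loadings
#' elsewhere; the factor correlation matrix interpolates between identity
#' and a random correlation matrix; uniquenesses are 1 - communality, kept
#' above \code{minUniqueness} by rescaling rows whose communality would be
#' too large.  Deterministic given \code{seed}.
#'
#' @param p number of manifest variables (p >= m).
#' @param m number of common factors.
#' @param blockAssignment optional length-p integer vector in 1..m giving
#'   each variable's dominant factor; round-robin when omitted.
#' @param loadingRange interval for dominant loadings (within (-1, 1)).
#' @param crossLoadingRange interval for cross-loadings.
#' @param factorCorrSpread in [0, 1): 0 gives orthogonal factors, larger
#'   values stronger random factor correlations.
#' @param minUniqueness lower bound for the uniquenesses, in (0, 1).
#' @param seed integer seed (required, for reproducibility).
#' @return a \linkS4class{FactorModel}.
#' @examples
#' simulateFactorModel(6, 2, seed = 7)
#' @export
simulateFactorModel <- function(p, m, blockAssignment = NULL,
                                loadingRange = c(0.5, 0.9),
                                crossLoadingRange = c(-0.2, 0.2),
                                factorCorrSpread = 0,
                                minUniqueness = 0.1,
                                seed) {
  stopifnot(p >= m, m >= 1, minUniqueness > 0, minUniqueness < 1,
            factorCorrSpread >= 0, factorCorrSpread < 1)
  if (max(abs(c(loadingRange, crossLoadingRange))) >= 1)
    stop("loading ranges must lie within (-1, 1)")
  if (missing(seed)) stop("'seed' is required")
  .withSeed(seed, {
    if (is.null(blockAssignment))
      blockAssignment <- rep_len(seq_len(m), p)
    stopifnot(length(blockAssignment) == p, all(blockAssignment %in% seq_len(m)))
    L <- matrix(stats::runif(p * m, crossLoadingRange[1], crossLoadingRange[2]),
                p, m)
    L[cbind(seq_len(p), blockAssignment)] <-
      stats::runif(p, loadingRange[1], loadingRange[2])
    Phi <- diag(1, m)
    if (factorCorrSpread > 0 && m > 1) {
      W <- matrix(stats::rnorm(m * m), m, m)
      R0 <- stats::cov2cor(crossprod(W) + diag(m))
      Phi <- (1 - factorCorrSpread) * diag(1, m) + factorCorrSpread * R0
    }
    # rescale rows whose communality would leave less than minUniqueness
    h2 <- rowSums((L %*% Phi) * L)
    over <- h2 > 1 - minUniqueness
    if (any(over))
      L[over, ] <- L[over, , drop = FALSE] *
        sqrt((1 - minUniqueness) / h2[over])
    factorModel(L, Phi, recomputeUniqueness = TRUE)
  })
}

#' Sample joint observations of manifest variables and factors
#'
#' Draws n i.i.d. rows of the stacked vector (X, xi) from the Gaussian
#' factor model: \eqn{\xi \sim N(0, \Phi)}, \eqn{\epsilon \sim N(0,
#' \Omega)}, \eqn{X = \Lambda \xi + \epsilon}.  The population covariance
#' of the rows is exactly the model-implied joint covariance.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param n number of rows (n >= 1).
#' @param seed integer seed (required).
#' @return n x (p + m) numeric matrix, columns named by variables then
#'   factors.
#' @export
sampleObservations <- function(model, n, seed) {
  stopifnot(is(model, "FactorModel"), n >= 1)
  if (missing(seed)) stop("'seed' is required")
  .withSeed(seed, {
    p <- nrow(model@loadings); m <- ncol(model@loadings)
    xi <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = model@factorCorr)
    xi <- matrix(xi, nrow = n, ncol = m)
    eps <- matrix(stats::rnorm(n * p), n, p) %*%
      diag(sqrt(model@uniqueVars), p)
    X <- xi %*% t(model@loadings) + eps
    out <- cbind(X, xi)
    colnames(out) <- c(rownames(model@loadings), colnames(model@loadings))
    out
  })
}

#' Monte-Carlo estimate of the symmetrized KL contribution
#'
#' Estimates the symmetrized Kullback-Leibler information between the
#' conditional law of X given xi and its marginal,
#' \deqn{\int\!\!\int f(x|\xi) g(\xi) \log\frac{f(x|\xi)}{f(x)}\,dx\,d\xi
#'   + \int\!\!\int f(x) g(\xi) \log\frac{f(x)}{f(x|\xi)}\,dx\,d\xi,}
#' by direct sampling with exact Gaussian log-densities: the first integral
#' averages the log-ratio over joint draws of (X, xi), the second over
#' independent draws of X and xi.  Both directed terms are returned along
#' with the Monte-Carlo standard error of the total.  The estimate is
#' consistent with the closed form \code{\link{klContribution}} and serves
#' as a density-level oracle for it.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param n number of Monte-Carlo draws per integral (>= 1e4 recommended).
#' @param seed integer seed (required).
#' @return list with \code{estimate}, \code{se}, \code{forward},
#'   \code{reverse} and \code{n}.
#' @export
mcKLEstimate <- function(model, n = 1e5, seed) {
  stopifnot(is(model, "FactorModel"), n >= 1)
  if (missing(seed)) stop("'seed' is required")
  .withSeed(seed, {
    p <- nrow(model@loadings)
    Sigma <- manifestBlock(impliedCovariance(model))
    w <- model@uniqueVars

    logRatio <- function(X, xi) {
      # log f(x|xi) - log f(x); f(x|xi) is diagonal N(Lambda xi, Omega)
      mu <- xi %*% t(model@loadings)
      Z <- X - mu
      logCond <- -0.5 * colSums(t(Z^2) / w) - 0.5 * sum(log(2 * pi * w))
      logCond - .logdMvnorm(X, Sigma)
    }

    joint <- sampleObservations(model, n,
                                seed = sample.int(.Machine$integer.max, 1))
    Xj <- joint[, seq_len(p), drop = FALSE]
    xij <- joint[, -seq_len(p), drop = FALSE]
    fwd <- logRatio(Xj, xij)

    indep <- sampleObservations(model, n,
                                seed = sample.int(.Machine$integer.max, 1))
    Xi2 <- indep[, seq_len(p), drop = FALSE]
    xi2 <- xij[sample.int(n), , drop = FALSE]   # independent pairing
    rev <- -logRatio(Xi2, xi2)

    est <- mean(fwd) + mean(rev)
    se <- sqrt(stats::var(fwd) / n + stats::var(rev) / n)
    list(estimate = est, se = se, forward = mean(fwd), reverse = mean(rev),
         n = n)
  })
}
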