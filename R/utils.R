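# Internal numerical helpers.

# Relative eigenvalue tolerance for positive-definiteness checks and the
# condition-number cap for factor-space transforms.
.pdTol <- 1e-10
.condCap <- 1e12

.isPositiveDefinite <- function(S, tol = .pdTol) {
  if (max(abs(S - t(S))) > 1e-8) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[length(ev)] > tol * max(abs(ev[1]), .Machine$double.eps)
}

.assertSquareNonsingular <- function(Q, what = "transform") {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop(sprintf("'%s' must be a square matrix", what), call. = FALSE)
  kappa <- kappa(Q, exact = TRUE)
  if (!is.finite(kappa) || kappa > .condCap)
    stop(sprintf("'%s' is singular or ill-conditioned (condition number %.3g)",
                 what, kappa), call. = FALSE)
  invisible(kappa)
}

# Resolve a subset given as indices or variable names; default = all.
.resolveSubset <- function(model, subset) {
  p <- nrow(model@loadings)
  if (is.null(subset)) return(seq_len(p))
  if (length(subset) == 0L) stop("subset must be non-empty", call. = FALSE)
  if (is.character(subset)) {
    idx <- match(subset, rownames(model@loadings))
    if (anyNA(idx))
      stop("unknown variable name(s): ",
           paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(subset)
    if (length(idx) == 0L || anyNA(idx) || any(idx < 1L) || any(idx > p))
      stop("subset indices must be within 1..", p, call. = FALSE)
  }
  if (length(idx) == 0L) stop("subset must be non-empty", call. = FALSE)
  if (anyDuplicated(idx)) stop("subset contains duplicate variables", call. = FALSE)
  idx
}

# Sign convention: flip v so its largest-magnitude entry is positive.
.orientVector <- function(v) {
  k <- which.max(abs(v))
  if (v[k] < 0) -v else v
}

# log-density of N(0, S) at the rows of x, via Cholesky.
.logdMvnorm <- function(x, S) {
  R <- chol(S)
  z <- forwardsolve(t(R), t(x))
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * ncol(S) * log(2 * pi)
}

# Evaluate a function under a temporary RNG state seeded by `seed`,
# restoring the caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
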