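# Shared fixtures and generators for the test suite.

table1 <- function() exampleModel("example1")
table3 <- function() exampleModel("example2")

# A batch of random models covering orthogonal and correlated factors,
# varying sizes; deterministic given the base seed.
randomModels <- function(nModels, baseSeed = 100) {
  lapply(seq_len(nModels), function(i) {
    p <- 3 + (i %% 6)          # 3..8 variables
    m <- 1 + (i %% min(3, p))  # 1..3 factors, m <= p
    spread <- c(0, 0.4, 0.7)[1 + (i %% 3)]
    simulateFactorModel(p, m, factorCorrSpread = spread,
                        seed = baseSeed + i)
  })
}

# Random nonsingular factor transform with bounded condition number.
randomTransform <- function(m, seed) {
  set.seed(seed)
  repeat {
    Q <- matrix(rnorm(m * m), m, m)
    if (kappa(Q, exact = TRUE) < 1e3) return(Q)
  }
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
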