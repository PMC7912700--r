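test_that("KL contributions reproduce the worked-example arithmetic", {
  m1 <- table1()
  expect_equal(klContribution(m1), 9.743727, tolerance = 1e-6)
  expect_equal(klContribution(m1, c("X4", "X5")), 6.330253, tolerance = 1e-6)
  pv <- variableContributions(m1)
  expect_equal(unname(pv),
               c(1.0496, 1.632272, 0.7316017, 0.8198362, 5.510417),
               tolerance = 1e-6)
  expect_equal(unname(variableContributions(table3())["X1"]), 1.205072,
               tolerance = 1e-6)
  expect_error(klContribution(m1, integer(0)), "non-empty")

  # no signal, no contribution
  m0 <- factorModel(matrix(0, 3, 2), uniqueVars = rep(1, 3))
  expect_equal(klContribution(m0), 0)
})

test_that("single-factor contributions match printed values and are scale-invariant", {
  m1 <- table1()
  m2 <- table3()
  expect_equal(factorContribution(m1, c(0, 1)), 6.607265, tolerance = 1e-6)
  g <- c(0.64, 0.37)                       # Spearman-g direction (X1 row)
  expect_equal(factorContribution(m2, g), 19.928238, tolerance = 1e-6)
  expect_equal(factorContribution(m2, c(0.5203, 0.8543)), 9.77,
               tolerance = 1e-3)
  for (cc in c(0.1, -3, 42))
    expect_equal(factorContribution(m2, cc * g), factorContribution(m2, g),
                 tolerance = 1e-12)
  expect_error(factorContribution(m1, c(0, 0)), "nonzero")
})

test_that("contributions are additive over variables and partitions (random models)", {
  for (mod in randomModels(200)) {
    pv <- variableContributions(mod)
    expect_equal(sum(pv), klContribution(mod), tolerance = 1e-10)
    p <- nManifest(mod)
    set.seed(p * 7 + nFactors(mod))
    cut <- sample(p - 1, 1)
    perm <- sample(p)
    g1 <- perm[seq_len(cut)]; g2 <- perm[-seq_len(cut)]
    expect_equal(klContribution(mod, g1) + klContribution(mod, g2),
                 klContribution(mod), tolerance = 1e-10)
  }
})

test_that("orthogonal factors decompose the total exactly (and by direct summation)", {
  for (mod in Filter(function(m) max(abs(factorCorr(m) - diag(nFactors(m)))) == 0,
                     randomModels(60))) {
    m <- nFactors(mod)
    perFac <- vapply(seq_len(m), function(j) {
      e <- numeric(m); e[j] <- 1
      factorContribution(mod, e)
    }, numeric(1))
    expect_equal(sum(perFac), klContribution(mod), tolerance = 1e-10)
    direct <- colSums(loadingMatrix(mod)^2 / uniqueVars(mod))
    expect_equal(unname(perFac), unname(direct), tolerance = 1e-10)
  }
})

test_that("marginal single-factor formula equals explicit Gaussian conditioning", {
  models <- randomModels(40)
  for (i in seq_along(models)) {
    mod <- models[[i]]
    set.seed(2000 + i)
    f <- rnorm(nFactors(mod))
    expect_equal(klContribution(mod) - conditionalKL(mod, f),
                 factorContribution(mod, f), tolerance = 1e-8)
  }
})

test_that("contribution report assembles ECD, RC and per-group totals", {
  m1 <- table1()
  rep1 <- contributionReport(m1)
  expect_equal(rep1@ecd, 0.9069224, tolerance = 1e-6)
  expect_equal(rep1@ecd, rep1@totalKL / (rep1@totalKL + 1), tolerance = 1e-12)
  expect_equal(sum(rep1@perVariable), rep1@totalKL, tolerance = 1e-10)
  expect_true(all(rep1@perFactor >= 0))

  # canonical factors of the full-vector analysis as the factor set
  dec <- canonicalDecomposition(m1)
  repc <- contributionReport(m1, factorSet = asplit(t(factorCoefs(dec)), 1L))
  expect_equal(unname(repc@rc[1]), 0.7223507, tolerance = 1e-6)

  groups <- list(arts = c("X1", "X2", "X3"), science = c("X4", "X5"))
  repg <- contributionReport(m1, groups = groups)
  expect_equal(sum(repg@perGroup), repg@totalKL, tolerance = 1e-10)

  # derived oblique factors: RCtilde of the verbal factor, RC sum above 1
  m2 <- table3()
  sg <- subgroupAnalysis(m2, list(g = "X1", pr = c("X2", "X3", "X4"),
                                  vb = c("X5", "X6")))
  fset <- lapply(sg, function(d) factorCoefs(d)[, 1])
  rep2 <- contributionReport(m2, factorSet = fset)
  expect_equal(unname(rep2@rcTilde["vb"]), 0.8239521, tolerance = 1e-6)
  expect_gt(sum(rep2@rc), 1)   # correlated factors, no renormalization
})
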