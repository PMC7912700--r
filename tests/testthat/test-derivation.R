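test_that("leading group factors reproduce the published coefficient matrices", {
  m1 <- table1()
  G1 <- selectLeadingFactors(m1, list(arts = c("X1", "X2", "X3"),
                                      science = c("X4", "X5")))
  expect_equal(unname(G1),
               rbind(c(0.9469837, 0.3212815), c(0.05738692, 0.998352)),
               tolerance = 1e-6)

  m2 <- table3()
  G2 <- selectLeadingFactors(m2, list(pr = c("X2", "X3", "X4"),
                                      vb = c("X5", "X6")))
  expect_equal(unname(G2),
               rbind(c(0.5201698, 0.8540629), c(0.9933367, -0.1152485)),
               tolerance = 1e-6)

  # group count must match the factor-space dimension
  expect_error(selectLeadingFactors(m1, list(a = 1, b = 2, c = 3)),
               "m = 2 groups")
})

test_that("derived oblique system reproduces the published loading tables", {
  m1 <- table1()
  sys1 <- deriveFactorSystem(m1, groups = list(arts = c("X1", "X2", "X3"),
                                               science = c("X4", "X5")))
  # printed table: columns eta(arts), eta(science)
  printed1 <- rbind(c(0.62, 0.19), c(0.80, -0.02), c(0.70, -0.22),
                    c(0.31, 0.49), c(-0.06, 0.94))
  expect_equal(unname(newLoadings(sys1)), printed1, tolerance = 0.011)
  expect_equal(factorCorrNew(sys1)["arts", "science"], 0.3750965,
               tolerance = 1e-6)

  m2 <- table3()
  sys2 <- deriveFactorSystem(m2, groups = list(pr = c("X2", "X3", "X4"),
                                               vb = c("X5", "X6")))
  printed2 <- rbind(c(0.49, 0.39), c(0.63, 0.01), c(0.89, 0.00),
                    c(0.48, 0.00), c(-0.01, 0.98), c(0.07, 0.79))
  expect_equal(unname(newLoadings(sys2)), printed2, tolerance = 0.011)

  # three derived factors in a two-dimensional space: pairwise correlations
  sg <- subgroupAnalysis(m2, list(g = "X1", pr = c("X2", "X3", "X4"),
                                  vb = c("X5", "X6")))
  f <- lapply(sg, function(d) factorCoefs(d)[, 1])
  Phi <- factorCorr(m2)
  corrOf <- function(a, b) drop(t(a) %*% Phi %*% b)
  expect_equal(c(corrOf(f$g, f$pr), corrOf(f$g, f$vb), corrOf(f$pr, f$vb)),
               c(0.8777901, 0.802284, 0.4182743), tolerance = 1e-6)
})

test_that("identity system and precondition errors behave as specified", {
  m1 <- table1()
  sysI <- deriveFactorSystem(m1, coefMatrix = diag(2))
  expect_equal(unname(newLoadings(sysI)), unname(loadingMatrix(m1)),
               tolerance = 1e-12)
  expect_equal(unname(factorCorrNew(sysI)), diag(2), tolerance = 1e-12)
  expect_equal(unname(contributions(sysI)),
               unname(colSums(loadingMatrix(m1)^2 / uniqueVars(m1))),
               tolerance = 1e-10)

  expect_error(deriveFactorSystem(m1, coefMatrix = matrix(1, 3, 3)), "2 x 2")
  expect_error(deriveFactorSystem(m1, coefMatrix = rbind(c(1, 1), c(1, 1))),
               "ill-conditioned")
  expect_error(deriveFactorSystem(m1), "coefMatrix.*groups")
})

test_that("re-parametrization is exact and contribution-preserving (random models)", {
  models <- randomModels(200)
  for (i in seq_along(models)) {
    mod <- models[[i]]
    m <- nFactors(mod)
    G0 <- randomTransform(m, seed = 7000 + i)
    sys <- deriveFactorSystem(mod, coefMatrix = G0)
    G <- coefMatrix(sys)
    L <- loadingMatrix(mod); Phi <- factorCorr(mod)
    expect_equal(newLoadings(sys) %*% G, L, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(newLoadings(sys) %*% factorCorrNew(sys) %*% t(newLoadings(sys)),
                 L %*% Phi %*% t(L), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(unname(diag(factorCorrNew(sys))), rep(1, m),
                 tolerance = 1e-10)
    # total KL of the oblique system equals the original total
    expect_equal(klContribution(asFactorModel(sys)), klContribution(mod),
                 tolerance = 1e-10)
  }
})

test_that("per-group contribution tables accompany group-derived systems", {
  m1 <- table1()
  groups <- list(arts = c("X1", "X2", "X3"), science = c("X4", "X5"))
  sys <- deriveFactorSystem(m1, groups = groups)
  cg <- sys@contributionsGroups
  expect_named(cg, c("arts", "science"))
  # each group's own factor dominates within the group, with RC near one
  expect_equal(unname(cg$arts$contributions["arts"]), 3.273574,
               tolerance = 1e-6)
  expect_equal(unname(cg$science$contributions["science"]), 6.163651,
               tolerance = 1e-6)
  expect_gt(cg$arts$rc["arts"], 0.9)
  expect_gt(cg$science$rc["science"], 0.9)
})
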