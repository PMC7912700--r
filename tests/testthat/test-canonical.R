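test_that("full-vector canonical analysis reproduces the worked example", {
  dec <- canonicalDecomposition(table1())
  expect_equal(rhoSq(dec), c(0.8755969, 0.7301191), tolerance = 1e-6)
  expect_equal(contributions(dec), c(7.038388, 2.705339), tolerance = 1e-6)
  expect_equal(unname(factorCoefs(dec)[, 1]), c(0.3154306, 0.9489486),
               tolerance = 1e-6)
  expect_equal(sum(contributions(dec)), totalKL(dec), tolerance = 1e-10)
  expect_equal(contributions(dec), rhoSq(dec) / (1 - rhoSq(dec)),
               tolerance = 1e-12)
  # ordering and unit-variance variates
  expect_true(all(diff(rhoSq(dec)) <= 0))
  Phi <- factorCorr(table1())
  for (j in 1:2)
    expect_equal(drop(t(factorCoefs(dec)[, j]) %*% Phi %*% factorCoefs(dec)[, j]),
                 1, tolerance = 1e-10)
  Sigma <- manifestBlock(impliedCovariance(table1()))
  B <- manifestCoefs(dec)
  for (j in 1:2) {
    expect_equal(drop(t(B[, j]) %*% Sigma %*% B[, j]), 1, tolerance = 1e-10)
    # corr(V_j, eta_j) = +rho_j under the sign convention
    covVE <- drop(t(B[, j]) %*% loadingMatrix(table1()) %*% Phi %*%
                    factorCoefs(dec)[, j])
    expect_equal(covVE, sqrt(rhoSq(dec)[j]), tolerance = 1e-10)
  }
})

test_that("subset analyses reproduce the group-level worked examples", {
  m1 <- table1()
  d13 <- canonicalDecomposition(m1, c("X1", "X2", "X3"))
  expect_equal(contributions(d13), c(3.273574, 0.1398995), tolerance = 1e-6)
  expect_equal(unname(factorCoefs(d13)[, 1]), c(0.9469837, 0.3212815),
               tolerance = 1e-6)
  d45 <- canonicalDecomposition(m1, 4:5)
  expect_equal(contributions(d45)[1], 6.163651, tolerance = 1e-6)
  expect_equal(unname(factorCoefs(d45)[, 1]), c(0.05738692, 0.998352),
               tolerance = 1e-6)

  # one-factor model: 1x1 eigenproblem closed form
  lam <- c(0.6, 0.8)
  ms <- factorModel(cbind(lam), recomputeUniqueness = TRUE)
  ds <- canonicalDecomposition(ms)
  a <- sum(lam^2 / (1 - lam^2))
  expect_equal(contributions(ds), a, tolerance = 1e-12)
  expect_equal(rhoSq(ds), a / (1 + a), tolerance = 1e-12)

  # single-variable subset: rho^2 is the squared multiple correlation
  for (i in 1:5) {
    di <- canonicalDecomposition(m1, i)
    expect_length(rhoSq(di), 1L)
    expect_equal(rhoSq(di), unname(communalities(m1)[i]), tolerance = 1e-10)
  }
})

test_that("trace identity and per-variable R^2 identity hold on random models", {
  for (mod in randomModels(200)) {
    dec <- canonicalDecomposition(mod)
    expect_equal(sum(contributions(dec)), klContribution(mod),
                 tolerance = 1e-8)
    Sigma <- manifestBlock(impliedCovariance(mod))
    R2 <- communalities(mod) / diag(Sigma)
    expect_equal(sum(contributions(dec)), sum(R2 / (1 - R2)),
                 tolerance = 1e-8)
  }
})

test_that("canonical analysis is invariant under nonsingular factor transforms", {
  mods <- randomModels(10)
  ref <- lapply(mods, function(m) rhoSq(canonicalDecomposition(m)))
  count <- 0
  for (i in seq_along(mods)) {
    for (s in 1:5) {
      count <- count + 1
      Q <- randomTransform(nFactors(mods[[i]]), seed = 3000 + count)
      mq <- transformModel(mods[[i]], Q)
      expect_equal(rhoSq(canonicalDecomposition(mq)), ref[[i]],
                   tolerance = 1e-8)
      # manifest-side rescaling leaves rho^2 unchanged too (diagonal P)
      expect_equal(rhoSq(canonicalDecomposition(mq, seq_len(nManifest(mq)))),
                   ref[[i]], tolerance = 1e-8)
    }
  }
  expect_equal(count, 50)
})

test_that("subgroup analysis decomposes the total contribution over a partition", {
  m1 <- table1()
  sg <- subgroupAnalysis(m1, list(a = 1:3, b = 4:5))
  grand <- sum(vapply(sg, function(d) sum(contributions(d)), numeric(1)))
  expect_equal(grand, klContribution(m1), tolerance = 1e-8)
  expect_equal(grand, 9.743727, tolerance = 1e-6)

  m2 <- table3()
  sg2 <- subgroupAnalysis(m2, list(g = "X1", pr = c("X2", "X3", "X4"),
                                   vb = c("X5", "X6")))
  expect_equal(unname(vapply(sg2, function(d) rhoSq(d)[1], numeric(1))),
               c(0.5465, 0.8254883, 0.959047), tolerance = 1e-6)
  # pair counts follow min(group size, m)
  expect_equal(unname(vapply(sg2, function(d) length(rhoSq(d)), numeric(1))),
               c(1, 2, 2))
  grand2 <- sum(vapply(sg2, function(d) sum(contributions(d)), numeric(1)))
  expect_equal(grand2, klContribution(m2), tolerance = 1e-8)

  # a single all-variable group is the plain full-vector analysis
  whole <- subgroupAnalysis(m1, list(all = 1:5))[[1]]
  expect_equal(rhoSq(whole), rhoSq(canonicalDecomposition(m1)),
               tolerance = 1e-12)

  expect_warning(subgroupAnalysis(m1, list(a = 1:3, b = 3:5)), "overlap")
})

test_that("near-unit canonical correlations are capped with a warning", {
  # valid but nearly degenerate: contribution large yet finite and exact
  L <- rbind(c(0.9999, 0), c(0, 0.7), c(0.5, 0.5))
  mod <- factorModel(L, recomputeUniqueness = TRUE)
  dec <- canonicalDecomposition(mod)
  expect_true(all(is.finite(contributions(dec))))
  expect_false(any(dec@capped))
  expect_equal(sum(contributions(dec)), klContribution(mod), tolerance = 1e-8)

  # uniqueness at machine level: rho^2 indistinguishable from 1
  Lcap <- rbind(c(sqrt(1 - 1e-13), 0), c(0, 0.7), c(0.5, 0.5))
  mcap <- factorModel(Lcap, recomputeUniqueness = TRUE)
  expect_warning(dcap <- canonicalDecomposition(mcap), "capped")
  expect_true(any(dcap@capped))
  expect_true(all(is.finite(contributions(dcap))))
})
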