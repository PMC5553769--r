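specTruth <- MixtureParams(c(0.8, 0.1, 0.1), c(4, 4), c(-4, -4),
                           sigmaSq = 0.25, sigmaSqG1 = 0.25,
                           sigmaSqG2 = 0.25)

test_that("the E-step delegates to the posterior computation", {
  set.seed(31)
  st <- randomStats(40)
  pr <- randomParams()
  expect_identical(posteriorProb(emEStep(st, pr)),
                   posteriorProb(posteriorProbabilities(st, pr)))
})

test_that("the M-step reproduces the literal update formulas", {
  set.seed(37)
  for (i in 1:10) {
    st <- randomStats(sample(10:60, 1))
    P <- matrix(runif(3 * length(st)), ncol = 3)
    P <- P / rowSums(P)
    got <- emMStep(st, PosteriorTable(geneIds(st), P))
    want <- oracleMStep(st, P)
    expect_equal(mixtureWeights(got), setNames(want$pi, c("null", "up", "down")),
                 tolerance = 1e-12)
    expect_equal(componentMeans(got)$up, want$mu1, tolerance = 1e-12)
    expect_equal(componentMeans(got)$down, want$mu2, tolerance = 1e-12)
    expect_equal(got@sigmaSq, want$sigmaSq, tolerance = 1e-12)
    expect_equal(got@sigmaSqG1, want$sigmaSqG1, tolerance = 1e-12)
    expect_equal(got@sigmaSqG2, want$sigmaSqG2, tolerance = 1e-12)
  }
})

test_that("hard responsibilities reduce the M-step to cluster moments", {
  d1 <- c(0.1, -0.2, 5, 6, -5, -6)
  d2 <- c(-0.1, 0.3, 6, 5, -6, -5)
  st <- TestStatTable(letters[1:6], d1, d2)
  P <- matrix(0, 6, 3)
  P[1:2, 1] <- 1; P[3:4, 2] <- 1; P[5:6, 3] <- 1
  got <- emMStep(st, PosteriorTable(geneIds(st), P))
  expect_equal(unname(mixtureWeights(got)), c(2, 2, 2) / 6)
  expect_equal(componentMeans(got)$up, c(5.5, 5.5))
  expect_equal(componentMeans(got)$down, c(-5.5, -5.5))
})

test_that("a dominant null component recovers the second-moment variance", {
  # nearly all responsibility on the null: sigma_g^2 -> m - 1 where m is
  # the null-weighted second moment per coordinate
  set.seed(43)
  st <- randomStats(200, scale = 2)
  eps <- 1e-9
  P <- cbind(rep(1 - 2 * eps, 200), rep(eps, 200), rep(eps, 200))
  got <- emMStep(st, PosteriorTable(geneIds(st), P))
  m <- mean(stat1(st)^2 + stat2(st)^2) / 2
  expect_equal(got@sigmaSq, m - 1, tolerance = 1e-6)
})

test_that("zero total responsibility raises a component-collapse error", {
  st <- randomStats(20)
  P <- cbind(rep(1, 20), rep(0, 20), rep(0, 20))
  expect_error(emMStep(st, PosteriorTable(geneIds(st), P)),
               class = "repmixCollapseError")
})

test_that("initialisation is deterministic per (seed, startIndex) and sign-correct", {
  set.seed(47)
  st <- randomStats(100)
  a <- emInitialize(st, seed = 5, startIndex = 2)
  b <- emInitialize(st, seed = 5, startIndex = 2)
  expect_true(mixtureParamsEqual(a, b))
  c1 <- emInitialize(st, seed = 5, startIndex = 3)
  expect_false(mixtureParamsEqual(a, c1))
  for (s in 1:5) {
    p <- emInitialize(st, seed = 9, startIndex = s)
    expect_true(all(p@mu1 > 0) && all(p@mu2 < 0))
    expect_equal(sum(mixtureWeights(p)), 1, tolerance = 1e-12)
  }
  expect_error(emInitialize(randomStats(5), 1), "at least 10")
})

test_that("the fit recovers known parameters from model-generated data", {
  est <- sapply(1:3, function(r) {
    sim <- sampleFromMixture(5000, specTruth, seed = 400 + r)
    fit <- emFit(sim$stats, emControl(nStarts = 5, seed = r))
    expect_true(fit@converged)
    p <- fittedParams(fit)
    c(p@pi, p@mu1, p@mu2)
  })
  m <- rowMeans(est)
  expect_lt(max(abs(m[1:3] - c(0.8, 0.1, 0.1))), 0.02)
  expect_lt(max(abs(m[4:5] - c(4, 4))), 0.15)
  expect_lt(max(abs(m[6:7] - c(-4, -4))), 0.15)
})

test_that("pure-null data yields no reproducibility calls", {
  # with no true signal the reproducible components degenerate into the
  # null's bulk; the null stays the dominant component and, decisively,
  # nothing is called reproducible
  nullTruth <- MixtureParams(c(1, 0, 0), c(1, 1), c(-1, -1),
                             sigmaSq = 1, sigmaSqG1 = 1, sigmaSqG2 = 1)
  sim <- sampleFromMixture(3000, nullTruth, seed = 71)
  fit <- suppressWarnings(emFit(sim$stats,
                                emControl(nStarts = 5, seed = 3,
                                          maxIter = 300)))
  w <- mixtureWeights(fit)
  expect_gte(w[["null"]], max(w[["up"]], w[["down"]]))
  calls <- classifyGenes(posteriorProbabilities(sim$stats, fittedParams(fit)),
                         alpha = 0.1)
  expect_equal(sum(calls$call), 0L)
})

test_that("fitting is bit-reproducible and RNG-clean", {
  sim <- sampleFromMixture(800, specTruth, seed = 12)
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  f1 <- emFit(sim$stats, emControl(nStarts = 4, seed = 21))
  f2 <- emFit(sim$stats, emControl(nStarts = 4, seed = 21))
  expect_true(mixtureParamsEqual(fittedParams(f1), fittedParams(f2)))
  expect_identical(loglikTrace(f1), loglikTrace(f2))
  expect_identical(f1@startIndex, f2@startIndex)
  # the fit derives all randomness from its own seed
  expect_identical(runif(1), before)
})

test_that("swapping the two studies swaps the fitted mean coordinates", {
  sim <- sampleFromMixture(2000, specTruth, seed = 88)
  swapped <- TestStatTable(geneIds(sim$stats), stat2(sim$stats),
                           stat1(sim$stats))
  f1 <- emFit(sim$stats, emControl(nStarts = 5, seed = 31))
  f2 <- emFit(swapped, emControl(nStarts = 5, seed = 31))
  expect_equal(componentMeans(f1)$up, rev(componentMeans(f2)$up),
               tolerance = 1e-6)
  expect_equal(componentMeans(f1)$down, rev(componentMeans(f2)$down),
               tolerance = 1e-6)
  expect_equal(unname(mixtureWeights(f1)), unname(mixtureWeights(f2)),
               tolerance = 1e-6)
  expect_equal(f1@loglik, f2@loglik, tolerance = 1e-8)
})

test_that("the winning restart has the maximal final log-likelihood", {
  sim <- sampleFromMixture(1500, specTruth, seed = 55)
  fit <- emFit(sim$stats, emControl(nStarts = 6, seed = 2))
  lls <- fit@restartLogliks
  expect_equal(fit@loglik, max(lls, na.rm = TRUE))
  expect_equal(fit@startIndex, which.max(lls))
})
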