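test_that("component covariances follow the structured form", {
  p0 <- MixtureParams(c(0.8, 0.1, 0.1), c(1, 1), c(-1, -1),
                      sigmaSq = 0, sigmaSqG1 = 0, sigmaSqG2 = 0)
  cv <- componentCovariances(p0)
  expect_equal(cv$null, diag(2))
  expect_equal(cv$up, diag(2))

  p <- MixtureParams(c(0.8, 0.1, 0.1), c(4, 4), c(-4, -4),
                     sigmaSq = 1, sigmaSqG1 = 2, sigmaSqG2 = 0.5)
  cv <- componentCovariances(p)
  expect_equal(cv$up, matrix(c(4, 2, 2, 4), 2))
  expect_equal(cv$null, 2 * diag(2))
  expect_equal(cv$down, matrix(c(2.5, 0.5, 0.5, 2.5), 2))

  set.seed(41)
  for (i in 1:20) {
    p <- randomParams()
    cv <- componentCovariances(p)
    ev <- eigen(cv$up - cv$null, symmetric = TRUE)$values
    expect_equal(sort(ev), c(0, 2 * p@sigmaSqG1), tolerance = 1e-12)
    for (S in cv) expect_true(all(eigen(S)$values > 0))
  }
})

test_that("invalid mixture parameters are rejected", {
  expect_error(MixtureParams(c(0.5, 0.5, 0.5), c(1, 1), c(-1, -1), 0, 0, 0),
               "sum to 1")
  expect_error(MixtureParams(c(0.8, 0.1, 0.1), c(1, 1), c(-1, -1), -1, 0, 0),
               "non-negative")
  expect_error(MixtureParams(c(0.8, 0.1, 0.1), c(NaN, 1), c(-1, -1), 0, 0, 0),
               "finite")
})

test_that("bivariate normal density matches closed forms and the dense oracle", {
  expect_equal(bvnDensity(c(0, 0), c(0, 0), diag(2)), 1 / (2 * pi))
  expect_equal(bvnDensity(c(1, 0), c(0, 0), diag(2)),
               exp(-0.5) / (2 * pi))
  set.seed(7)
  for (i in 1:25) {
    m <- rnorm(2, 0, 3)
    A <- matrix(rnorm(4), 2)
    S <- crossprod(A) + 0.1 * diag(2)
    x <- rnorm(2, 0, 4)
    expect_equal(bvnDensity(x, m, S, log = TRUE),
                 oracleLogDensity(x, m, S), tolerance = 1e-12)
  }
  expect_error(bvnDensity(c(0, 0), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(bvnDensity(c(0, 0), c(0, 0), matrix(c(1, 0.5, -0.5, 1), 2)),
               "symmetric")
})

test_that("posterior probabilities follow the mixture Bayes rule", {
  # degenerate weights: everything is null
  st <- randomStats(8)
  pDeg <- MixtureParams(c(1, 0, 0), c(1, 1), c(-1, -1), 0.5, 1, 1)
  expect_equal(unname(posteriorNull(posteriorProbabilities(st, pDeg))),
               rep(1, 8))

  # symmetric model at the origin gives equal up/down posteriors
  pSym <- MixtureParams(c(0.6, 0.2, 0.2), c(2, 2), c(-2, -2), 0.3, 0.7, 0.7)
  origin <- TestStatTable("o", 0, 0)
  P <- posteriorProb(posteriorProbabilities(origin, pSym))
  expect_equal(P[1, "p1"], P[1, "p2"], tolerance = 1e-14)

  # 5-gene table against the enumerated dense-matrix oracle
  set.seed(11)
  st5 <- randomStats(5)
  pr <- randomParams()
  expect_equal(unname(posteriorProb(posteriorProbabilities(st5, pr))),
               unname(oraclePosterior(st5, pr)), tolerance = 1e-10)
})

test_that("posteriors are normalised and finite for extreme statistics", {
  set.seed(13)
  for (i in 1:20) {
    pr <- randomParams()
    st <- TestStatTable(c("a", "b", "c", "d"),
                        c(1e3, -1e3, 45, rnorm(1)),
                        c(1e3, 1e3, -60, rnorm(1)))
    P <- posteriorProb(posteriorProbabilities(st, pr))
    expect_true(all(is.finite(P)))
    expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  }
})

test_that("reflecting the statistics with mirrored parameters swaps p1 and p2", {
  set.seed(17)
  st <- randomStats(30)
  pr <- randomParams()
  mirrored <- MixtureParams(pr@pi[c(1, 3, 2)], -pr@mu2, -pr@mu1,
                            pr@sigmaSq, pr@sigmaSqG2, pr@sigmaSqG1)
  refl <- TestStatTable(geneIds(st), -stat1(st), -stat2(st))
  P1 <- posteriorProb(posteriorProbabilities(st, pr))
  P2 <- posteriorProb(posteriorProbabilities(refl, mirrored))
  expect_identical(unname(P1[, c("p0", "p1", "p2")]),
                   unname(P2[, c("p0", "p2", "p1")]))
})

test_that("log-likelihood matches closed form and oracle, and is additive", {
  one <- TestStatTable("g", 0, 0)
  pNull <- MixtureParams(c(1, 0, 0), c(1, 1), c(-1, -1), 0, 1, 1)
  expect_equal(logLikelihood(one, pNull), log(1 / (2 * pi)))

  set.seed(23)
  for (i in 1:10) {
    st <- randomStats(sample(5:100, 1))
    pr <- randomParams()
    ll <- logLikelihood(st, pr)
    expect_equal(ll, oracleLogLik(st, pr), tolerance = 1e-8)
    dup <- TestStatTable(c(geneIds(st), paste0(geneIds(st), "_b")),
                         c(stat1(st), stat1(st)), c(stat2(st), stat2(st)))
    expect_equal(logLikelihood(dup, pr), 2 * ll, tolerance = 1e-10)
  }
  expect_error(TestStatTable(character(), numeric(), numeric()),
               "at least one gene")
})
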