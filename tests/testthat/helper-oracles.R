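# Independent oracles and fixture generators. The oracles deliberately
# take the generic dense-matrix route (solve(), det(), explicit loops)
# rather than the structured closed forms used by the package.

oracleLogDensity <- function(x, mean, sigma) {
  quad <- as.numeric(t(x - mean) %*% solve(sigma) %*% (x - mean))
  -log(2 * pi) - 0.5 * log(det(sigma)) - 0.5 * quad
}

oracleMixtureDensities <- function(stats, params) {
  cv <- componentCovariances(params)
  mns <- componentMeans(params)
  d <- as.data.frame(stats)
  t(vapply(seq_len(nrow(d)), function(g) {
    vapply(1:3, function(l) {
      exp(oracleLogDensity(c(d$d1[g], d$d2[g]), mns[[l]], cv[[l]]))
    }, numeric(1))
  }, numeric(3)))
}

oraclePosterior <- function(stats, params) {
  phi <- oracleMixtureDensities(stats, params)
  w <- sweep(phi, 2, mixtureWeights(params), "*")
  w / rowSums(w)
}

oracleLogLik <- function(stats, params) {
  phi <- oracleMixtureDensities(stats, params)
  sum(log(as.numeric(phi %*% mixtureWeights(params))))
}

# Literal loop transcription of the five closed-form M-step updates.
# P columns: responsibilities of the null, up, down components.
oracleMStep <- function(stats, P, minVar = 1e-8) {
  d <- as.data.frame(stats)
  p <- nrow(d)
  w <- c(sum(P[, 1]), sum(P[, 2]), sum(P[, 3]))
  pi <- w / p
  mu1 <- c(sum(P[, 2] * d$d1), sum(P[, 2] * d$d2)) / w[2]
  mu2 <- c(sum(P[, 3] * d$d1), sum(P[, 3] * d$d2)) / w[3]
  m0 <- sum(P[, 1] * (d$d1^2 + d$d2^2)) / (2 * w[1])
  s1 <- 0
  for (g in seq_len(p))
    s1 <- s1 + P[g, 2] * (d$d1[g] - mu1[1])^2 + P[g, 2] * (d$d2[g] - mu1[2])^2
  s2 <- 0
  for (g in seq_len(p))
    s2 <- s2 + P[g, 3] * (d$d1[g] - mu2[1])^2 + P[g, 3] * (d$d2[g] - mu2[2])^2
  list(pi = pi, mu1 = mu1, mu2 = mu2,
       sigmaSq = max(m0 - 1, minVar),
       sigmaSqG1 = max(s1 / (2 * w[2]) - m0, minVar),
       sigmaSqG2 = max(s2 / (2 * w[3]) - m0, minVar))
}

randomParams <- function() {
  pi <- runif(3, 0.1, 1)
  pi <- pi / sum(pi)
  MixtureParams(pi = pi,
                mu1 = runif(2, 0.5, 6), mu2 = -runif(2, 0.5, 6),
                sigmaSq = runif(1, 0, 2),
                sigmaSqG1 = runif(1, 0, 3), sigmaSqG2 = runif(1, 0, 3))
}

randomStats <- function(n, scale = 5) {
  TestStatTable(sprintf("g%04d", seq_len(n)),
                rnorm(n, 0, scale), rnorm(n, 0, scale))
}

# Draw statistic pairs directly from a given mixture (Cholesky per
# component) -- the fixture for parameter-recovery checks.
sampleFromMixture <- function(n, params, seed) {
  withr::with_seed(seed, {
    comp <- sample.int(3, n, replace = TRUE, prob = mixtureWeights(params))
    cv <- componentCovariances(params)
    mns <- componentMeans(params)
    z <- matrix(rnorm(2 * n), nrow = 2)
    d <- matrix(0, n, 2)
    for (l in 1:3) {
      idx <- which(comp == l)
      if (length(idx))
        d[idx, ] <- t(mns[[l]] + t(chol(cv[[l]])) %*% z[, idx, drop = FALSE])
    }
    list(stats = TestStatTable(sprintf("g%05d", seq_len(n)), d[, 1], d[, 2]),
         component = comp - 1L)
  })
}

mixtureParamsEqual <- function(a, b, tolerance = 0) {
  isTRUE(all.equal(
    c(a@pi, a@mu1, a@mu2, a@sigmaSq, a@sigmaSqG1, a@sigmaSqG2),
    c(b@pi, b@mu1, b@mu2, b@sigmaSq, b@sigmaSqG1, b@sigmaSqG2),
    tolerance = tolerance))
}
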