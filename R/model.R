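#' Component covariance matrices
#'
#' Builds the three structured 2x2 covariances of the mixture from the
#' variance parameters: the null component has
#' \eqn{\Sigma_0 = (\sigma_g^2 + 1) I_2} (the two studies' statistics are
#' uncorrelated for irreproducible genes), while the reproducible
#' components add a rank-one between-study term,
#' \eqn{\Sigma_k = (\sigma_g^2 + 1) I_2 + \sigma_{Gk}^2 J_2}, so their
#' off-diagonal equals \eqn{\sigma_{Gk}^2}.
#'
#' @param params a [MixtureParams-class].
#' @return Named list of three symmetric positive-definite 2x2 matrices
#'   (`null`, `up`, `down`).
#' @examples
#' p <- MixtureParams(c(0.8, 0.1, 0.1), c(4, 4), c(-4, -4), 1, 2, 2)
#' componentCovariances(p)$up  # [[4, 2], [2, 4]]
#' @export
componentCovariances <- function(params) {
  stopifnot(is(params, "MixtureParams"))
  validObject(params)
  base <- params@sigmaSq + 1
  I2 <- diag(2)
  J2 <- matrix(1, 2, 2)
  list(null = base * I2,
       up   = base * I2 + params@sigmaSqG1 * J2,
       down = base * I2 + params@sigmaSqG2 * J2)
}

#' Bivariate normal density
#'
#' Density of a bivariate normal at a point, computed from the closed-form
#' 2x2 inverse and determinant. Work is done in log space; extreme points
#' give an exact log density rather than underflowing.
#'
#' @param x numeric(2) evaluation point.
#' @param mean numeric(2) mean vector.
#' @param sigma 2x2 symmetric positive-definite covariance matrix.
#' @param log if TRUE return the log density.
#' @return A single non-negative density (or its log).
#' @examples
#' bvnDensity(c(0, 0), c(0, 0), diag(2))  # 1 / (2 * pi)
#' @export
bvnDensity <- function(x, mean, sigma, log = FALSE) {
  stopifnot(length(x) == 2L, length(mean) == 2L,
            is.matrix(sigma), all(dim(sigma) == 2L))
  if (any(!is.finite(x)) || any(!is.finite(mean)) || any(!is.finite(sigma)))
    stop("non-finite arguments to bvnDensity")
  if (abs(sigma[1, 2] - sigma[2, 1]) > 1e-8 * (1 + max(abs(sigma))))
    stop("covariance matrix must be symmetric")
  a <- sigma[1, 1]; d <- sigma[2, 2]; b <- (sigma[1, 2] + sigma[2, 1]) / 2
  det <- a * d - b * b
  if (a <= 0 || det <= 0)
    stop("covariance matrix must be positive definite")
  u <- x[1] - mean[1]; v <- x[2] - mean[2]
  quad <- (d * u * u - 2 * b * u * v + a * v * v) / det
  ld <- -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
  if (log) ld else exp(ld)
}

# Log densities of all genes under all three components, exploiting the
# equal-diagonal structure of the covariances: for Sigma = aI + bJ the
# inverse quadratic form is (a+b)(u^2+v^2) - 2b... computed directly from
# [[a+b, b],[b, a+b]] with det = (a+b)^2 - b^2.
.componentLogDensities <- function(d1, d2, params) {
  base <- params@sigmaSq + 1
  out <- matrix(0, length(d1), 3L)
  means <- list(c(0, 0), params@mu1, params@mu2)
  offs <- c(0, params@sigmaSqG1, params@sigmaSqG2)
  for (l in 1:3) {
    a <- base + offs[l]; b <- offs[l]
    det <- a * a - b * b
    u <- d1 - means[[l]][1]; v <- d2 - means[[l]][2]
    quad <- (a * (u * u + v * v) - 2 * b * u * v) / det
    out[, l] <- -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
  }
  out
}

#' Posterior component probabilities
#'
#' For every gene, the posterior probability that its statistic pair came
#' from the null, up or down component:
#' \deqn{p_{gl} = \pi_l \phi(d_{g1}, d_{g2} \mid \mu_l, \Sigma_l) /
#'   \sum_\ell \pi_\ell \phi(d_{g1}, d_{g2} \mid \mu_\ell, \Sigma_\ell).}
#' Computed entirely in log space with log-sum-exp normalisation, so very
#' large statistics (|d| in the hundreds) still yield finite, normalised
#' posteriors.
#'
#' @param stats a [TestStatTable-class].
#' @param params a [MixtureParams-class].
#' @return A [PosteriorTable-class].
#' @seealso [classifyGenes()] which thresholds the `p0` column.
#' @rdname posteriorProbabilities
#' @export
setMethod("posteriorProbabilities", c("TestStatTable", "MixtureParams"),
  function(stats, params) {
    validObject(stats); validObject(params)
    ld <- .componentLogDensities(stats@d1, stats@d2, params)
    lw <- sweep(ld, 2L, log(params@pi), "+")
    lse <- .rowLogSumExp(lw)
    PosteriorTable(stats@geneIds, exp(lw - lse))
  })

#' Mixture log-likelihood
#'
#' \eqn{\ell(\theta) = \sum_g \log \sum_l \pi_l \phi(d_{g1}, d_{g2} \mid
#' \mu_l, \Sigma_l)}, evaluated with the same log-space machinery as the
#' posteriors.
#'
#' @param stats a [TestStatTable-class].
#' @param params a [MixtureParams-class].
#' @return A single finite number.
#' @rdname logLikelihood
#' @export
setMethod("logLikelihood", c("TestStatTable", "MixtureParams"),
  function(stats, params) {
    validObject(stats); validObject(params)
    if (length(stats) == 0L) stop("empty test-statistic table")
    lw <- sweep(.componentLogDensities(stats@d1, stats@d2, params),
                2L, log(params@pi), "+")
    sum(.rowLogSumExp(lw))
  })
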