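#' @describeIn TestStatTable-class compact display.
#' @param object a `TestStatTable`.
#' @export
setMethod("show", "TestStatTable", function(object) {
  n <- length(object)
  cat(sprintf("TestStatTable with %d gene%s\n", n, if (n == 1) "" else "s"))
  cat(sprintf("  discordant signs: %d\n", sum(object@d1 * object@d2 < 0)))
  k <- min(n, 4L)
  for (i in seq_len(k))
    cat(sprintf("  %s: d1 = %.3f, d2 = %.3f\n",
                object@geneIds[i], object@d1[i], object@d2[i]))
  if (n > k) cat(sprintf("  ... and %d more\n", n - k))
})

#' @describeIn MixtureParams-class compact display.
#' @param object a `MixtureParams`.
#' @export
setMethod("show", "MixtureParams", function(object) {
  cat("MixtureParams (3-component constrained bivariate Gaussian mixture)\n")
  cat(sprintf("  weights (null/up/down): %.4f / %.4f / %.4f\n",
              object@pi[1], object@pi[2], object@pi[3]))
  cat(sprintf("  mu_up   = (%.3f, %.3f)\n", object@mu1[1], object@mu1[2]))
  cat(sprintf("  mu_down = (%.3f, %.3f)\n", object@mu2[1], object@mu2[2]))
  cat(sprintf("  sigma_g^2 = %.4f, sigma_G1^2 = %.4f, sigma_G2^2 = %.4f\n",
              object@sigmaSq, object@sigmaSqG1, object@sigmaSqG2))
})

#' @describeIn PosteriorTable-class compact display.
#' @param object a `PosteriorTable`.
#' @export
setMethod("show", "PosteriorTable", function(object) {
  cat(sprintf("PosteriorTable with %d genes\n", length(object)))
  cat(sprintf("  mean p0 (local fdr): %.4f\n", mean(object@prob[, 1])))
  cat(sprintf("  genes with p0 < 0.05: %d\n",
              sum(object@prob[, 1] < 0.05)))
})

#' @describeIn EMFit-class fit summary.
#' @param object an `EMFit`.
#' @export
setMethod("show", "EMFit", function(object) {
  cat("EMFit\n")
  cat(sprintf("  log-likelihood: %.4f (%sconverged in %d iterations)\n",
              object@loglik, if (object@converged) "" else "NOT ",
              object@nIter))
  cat(sprintf("  winning restart: %d of %d (%d collapsed)\n",
              object@startIndex, length(object@restartLogliks),
              sum(is.na(object@restartLogliks))))
  if (object@nDescents > 0L)
    cat(sprintf("  note: %d non-ascending iteration(s) (moment-matching M-step)\n",
                object@nDescents))
  show(object@params)
})

#' @describeIn PValuePair-class compact display.
#' @param object a `PValuePair`.
#' @export
setMethod("show", "PValuePair", function(object) {
  cat(sprintf("PValuePair with %d genes\n", length(object@geneIds)))
  cat(sprintf("  max-p < 0.05: %d genes\n",
              sum(pmax(object@p1, object@p2) < 0.05)))
})

#' @describeIn SimulationConfig-class configuration display.
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (two replicate two-group studies)\n")
  cat(sprintf("  %d genes, %d samples per group, %.1f%% reproducible (%.0f%% up)\n",
              object@nGenes, object@nPerGroup,
              100 * object@propReproducible, 100 * object@propUp))
  cat(sprintf("  effects: mu=%g alpha~N(0,%g^2) beta=%g ab~N(0,%g^2)\n",
              object@mu, object@sdAlpha, object@beta, object@sdAB))
  cat(sprintf("  diff: delta=%g gamma~N(+-%g,%g^2) gb~N(0,%g^2) eps~N(0,%g^2)\n",
              object@delta, object@muGamma, object@sdGamma, object@sdGB,
              object@sdEps))
})
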