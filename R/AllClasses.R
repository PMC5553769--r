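#' @import methods
#' @importFrom stats quantile rnorm runif sd setNames var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Paired test statistics from two replicate studies
#'
#' Holds one two-sample test statistic per gene from each of two replicate
#' studies. These pairs are the observations of the three-component
#' bivariate Gaussian mixture: an irreproducible (null) component centred
#' at the origin and two reproducible components for consistently up- and
#' down-regulated genes.
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot d1,d2 numeric vectors of finite test statistics from study 1 and
#'   study 2, parallel to `geneIds`.
#'
#' @seealso [TestStatTable()] for the constructor, [pairStudies()] to build
#'   one from two per-study statistic vectors.
#' @exportClass TestStatTable
setClass("TestStatTable",
  representation(geneIds = "character", d1 = "numeric", d2 = "numeric"))

setValidity("TestStatTable", function(object) {
  msg <- NULL
  n <- length(object@geneIds)
  if (n < 1L)
    msg <- c(msg, "at least one gene is required")
  if (length(object@d1) != n || length(object@d2) != n)
    msg <- c(msg, "geneIds, d1 and d2 must have equal length")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, sprintf("duplicated gene id(s): %s",
      paste(unique(object@geneIds[duplicated(object@geneIds)]), collapse = ", ")))
  if (!all(is.finite(object@d1)) || !all(is.finite(object@d2)))
    msg <- c(msg, "test statistics must be finite")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TestStatTable
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param d1,d2 finite per-gene test statistics from study 1 and study 2.
#' @return A [TestStatTable-class] object.
#' @examples
#' TestStatTable(c("a", "b"), c(1.2, -0.4), c(0.8, 0.1))
#' @export
TestStatTable <- function(geneIds, d1, d2) {
  new("TestStatTable", geneIds = as.character(geneIds),
      d1 = as.numeric(d1), d2 = as.numeric(d2))
}

#' Parameters of the constrained three-component bivariate mixture
#'
#' The mixture has a zero-mean null component with covariance
#' \eqn{\Sigma_0 = (\sigma_g^2 + 1) I_2}, and two reproducible components
#' with means \eqn{\mu_1} (both entries positive after label
#' normalisation) and \eqn{\mu_2} (both negative), and covariances
#' \eqn{\Sigma_k = (\sigma_g^2 + 1) I_2 + \sigma_{Gk}^2 J_2}. The shared
#' \eqn{\sigma_g^2} is the between-study variance: it inflates every
#' component's sampling variance (which is 1 on the test-statistic scale),
#' while \eqn{\sigma_{G1}^2, \sigma_{G2}^2} are the spreads of the true
#' effects within the up and down components and also give the
#' between-study covariance of the reproducible components.
#'
#' @slot pi numeric(3) mixture weights (null, up, down), summing to 1.
#' @slot mu1,mu2 numeric(2) means of the up and down components.
#' @slot sigmaSq shared between-study variance \eqn{\sigma_g^2 \ge 0}.
#' @slot sigmaSqG1,sigmaSqG2 effect-spread variances
#'   \eqn{\sigma_{G1}^2, \sigma_{G2}^2 \ge 0}.
#'
#' @seealso [MixtureParams()], [componentCovariances()], [emFit()]
#' @exportClass MixtureParams
setClass("MixtureParams",
  representation(pi = "numeric", mu1 = "numeric", mu2 = "numeric",
                 sigmaSq = "numeric", sigmaSqG1 = "numeric",
                 sigmaSqG2 = "numeric"))

setValidity("MixtureParams", function(object) {
  msg <- NULL
  if (length(object@pi) != 3L || any(!is.finite(object@pi)))
    msg <- c(msg, "pi must be 3 finite weights")
  else {
    if (any(object@pi < 0)) msg <- c(msg, "mixture weights must be non-negative")
    if (abs(sum(object@pi) - 1) > 1e-8) msg <- c(msg, "mixture weights must sum to 1")
  }
  if (length(object@mu1) != 2L || any(!is.finite(object@mu1)))
    msg <- c(msg, "mu1 must be 2 finite values")
  if (length(object@mu2) != 2L || any(!is.finite(object@mu2)))
    msg <- c(msg, "mu2 must be 2 finite values")
  for (s in c("sigmaSq", "sigmaSqG1", "sigmaSqG2")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("%s must be a single finite non-negative value", s))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct MixtureParams
#'
#' @param pi numeric(3) component weights (null, up, down); must sum to 1.
#' @param mu1,mu2 numeric(2) means of the up- and down-regulated components.
#' @param sigmaSq shared between-study variance \eqn{\sigma_g^2}.
#' @param sigmaSqG1,sigmaSqG2 effect-spread variances of the two
#'   reproducible components.
#' @return A [MixtureParams-class] object.
#' @examples
#' MixtureParams(pi = c(0.8, 0.1, 0.1), mu1 = c(4, 4), mu2 = c(-4, -4),
#'               sigmaSq = 0.25, sigmaSqG1 = 0.25, sigmaSqG2 = 0.25)
#' @export
MixtureParams <- function(pi, mu1, mu2, sigmaSq, sigmaSqG1, sigmaSqG2) {
  new("MixtureParams", pi = as.numeric(pi), mu1 = as.numeric(mu1),
      mu2 = as.numeric(mu2), sigmaSq = as.numeric(sigmaSq),
      sigmaSqG1 = as.numeric(sigmaSqG1), sigmaSqG2 = as.numeric(sigmaSqG2))
}

#' Per-gene posterior component probabilities
#'
#' One row per gene with posterior probabilities of the null (`p0`), up
#' (`p1`) and down (`p2`) components given the pair of test statistics.
#' `p0` is the local false discovery rate used for classification.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot prob numeric matrix (genes x 3) with columns `p0`, `p1`, `p2`;
#'   rows sum to 1.
#' @seealso [posteriorProbabilities()], [classifyGenes()]
#' @exportClass PosteriorTable
setClass("PosteriorTable",
  representation(geneIds = "character", prob = "matrix"))

setValidity("PosteriorTable", function(object) {
  msg <- NULL
  p <- object@prob
  if (!is.numeric(p) || ncol(p) != 3L)
    msg <- c(msg, "prob must be a numeric matrix with 3 columns")
  else {
    if (nrow(p) != length(object@geneIds))
      msg <- c(msg, "prob must have one row per gene id")
    if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
      msg <- c(msg, "probabilities must lie in [0, 1]")
    else if (any(abs(rowSums(p) - 1) > 1e-8))
      msg <- c(msg, "posterior rows must sum to 1")
  }
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene ids must be unique")
  if (is.null(msg)) TRUE else msg
})

PosteriorTable <- function(geneIds, prob) {
  colnames(prob) <- c("p0", "p1", "p2")
  new("PosteriorTable", geneIds = as.character(geneIds), prob = prob)
}

#' Two-group expression study
#'
#' A thin [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass for one study of a two-group design: an `exprs` assay of
#' normalised, transformed measurements (genes x samples) and a per-sample
#' `group` column in `colData` coded 1 = control, 2 = treatment. Each group
#' must contain at least two samples so a pooled-variance t statistic is
#' defined.
#'
#' @seealso [ExpressionStudy()], [tStatistics()]
#' @exportClass ExpressionStudy
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- NULL
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'exprs' assay is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "exprs"))))
    msg <- c(msg, "expression values must be finite (no missing values)")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    grp <- cd$group
    if (!all(grp %in% c(1L, 2L)))
      msg <- c(msg, "group labels must be 1 (control) or 2 (treatment)")
    else if (sum(grp == 1L) < 2L || sum(grp == 2L) < 2L)
      msg <- c(msg, "each group needs at least 2 samples")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique gene ids are required as rownames")
  if (is.null(msg)) TRUE else msg
})

#' Construct an ExpressionStudy
#'
#' @param exprs numeric matrix, genes x samples, on a normalised and
#'   transformed (e.g. log) scale.
#' @param group integer vector of per-sample group labels, 1 = control,
#'   2 = treatment; length `ncol(exprs)`.
#' @param geneIds gene identifiers; defaults to `rownames(exprs)`.
#' @param studyId identifier stored in the object metadata.
#' @return An [ExpressionStudy-class] object.
#' @examples
#' m <- matrix(rnorm(30), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
#' ExpressionStudy(m, group = c(1, 1, 1, 2, 2, 2), studyId = "toy")
#' @export
ExpressionStudy <- function(exprs, group, geneIds = rownames(exprs),
                            studyId = "study") {
  exprs <- as.matrix(exprs)
  if (is.null(geneIds))
    stop("gene ids are required (rownames or geneIds=)")
  rownames(exprs) <- as.character(geneIds)
  if (is.null(colnames(exprs)))
    colnames(exprs) <- sprintf("sample%02d", seq_len(ncol(exprs)))
  if (length(group) != ncol(exprs))
    stop("'group' must have one label per sample column")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(group = as.integer(group),
                                   row.names = colnames(exprs)))
  S4Vectors::metadata(se)$studyId <- studyId
  new("ExpressionStudy", se)
}

#' EM configuration
#'
#' Controls the EM fit: number of random restarts, iteration cap, the two
#' stopping tolerances (largest absolute parameter change, and absolute
#' change in log-likelihood, both of which must be met), the master seed
#' from which all restart initialisations are derived, and the floor
#' applied to variance estimates to keep the component covariances
#' positive definite.
#'
#' @slot nStarts integer >= 1, number of random restarts (default 10).
#' @slot maxIter integer iteration cap per restart (default 1000).
#' @slot tolParam parameter-change tolerance \eqn{\delta_1} (default 1e-4).
#' @slot tolLoglik log-likelihood-change tolerance \eqn{\delta_2}
#'   (default 1e-6).
#' @slot seed integer master seed.
#' @slot minVar variance floor (default 1e-8).
#' @slot verbose logical; report per-restart final log-likelihoods.
#' @seealso [emControl()], [emFit()]
#' @exportClass EMConfig
setClass("EMConfig",
  representation(nStarts = "integer", maxIter = "integer",
                 tolParam = "numeric", tolLoglik = "numeric",
                 seed = "integer", minVar = "numeric", verbose = "logical"))

setValidity("EMConfig", function(object) {
  msg <- NULL
  if (object@nStarts < 1L) msg <- c(msg, "nStarts must be >= 1")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
  if (object@tolParam <= 0) msg <- c(msg, "tolParam must be > 0")
  if (object@tolLoglik <= 0) msg <- c(msg, "tolLoglik must be > 0")
  if (object@minVar <= 0) msg <- c(msg, "minVar must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname EMConfig-class
#' @param nStarts,maxIter,tolParam,tolLoglik,seed,minVar,verbose see slots.
#' @return An [EMConfig-class] object.
#' @export
emControl <- function(nStarts = 10L, maxIter = 1000L, tolParam = 1e-4,
                      tolLoglik = 1e-6, seed = 1L, minVar = 1e-8,
                      verbose = FALSE) {
  new("EMConfig", nStarts = as.integer(nStarts), maxIter = as.integer(maxIter),
      tolParam = tolParam, tolLoglik = tolLoglik, seed = as.integer(seed),
      minVar = minVar, verbose = isTRUE(verbose))
}

#' Result of an EM fit
#'
#' @slot params fitted [MixtureParams-class] of the winning restart, with
#'   components relabelled so label 1 is the up component.
#' @slot loglik final log-likelihood of the winning restart.
#' @slot loglikTrace per-iteration log-likelihood of the winning restart.
#' @slot converged TRUE if both stopping conditions were met.
#' @slot nIter iterations run by the winning restart.
#' @slot startIndex index of the winning restart.
#' @slot restartLogliks final log-likelihood of every restart (NA where a
#'   restart collapsed).
#' @slot nDescents number of iterations of the winning restart in which
#'   the log-likelihood decreased by more than `1e-6 * |loglik|`. The
#'   closed-form M-step matches moments rather than exactly maximising
#'   the observed-data log-likelihood, so the trace need not ascend;
#'   this slot records how non-monotone the winning run was.
#' @seealso [emFit()]
#' @exportClass EMFit
setClass("EMFit",
  representation(params = "MixtureParams", loglik = "numeric",
                 loglikTrace = "numeric", converged = "logical",
                 nIter = "integer", startIndex = "integer",
                 restartLogliks = "numeric", nDescents = "integer"))

#' Paired two-sided p-values for the max-p baseline
#'
#' Carries, per gene, the two-sided p-value of each study's statistic plus
#' the statistic signs (needed to report a call direction, which the
#' p-values alone cannot provide — the known blind spot of p-value-only
#' reproducibility rules).
#'
#' @slot geneIds character gene identifiers.
#' @slot p1,p2 per-study two-sided p-values in \[0, 1\].
#' @slot sign1,sign2 signs (-1, 0, 1) of the underlying statistics.
#' @seealso [twoSidedP()], [partialConjunction()]
#' @exportClass PValuePair
setClass("PValuePair",
  representation(geneIds = "character", p1 = "numeric", p2 = "numeric",
                 sign1 = "numeric", sign2 = "numeric"))

setValidity("PValuePair", function(object) {
  msg <- NULL
  n <- length(object@geneIds)
  if (length(object@p1) != n || length(object@p2) != n ||
      length(object@sign1) != n || length(object@sign2) != n)
    msg <- c(msg, "all slots must have equal length")
  for (s in c("p1", "p2")) {
    v <- slot(object, s)
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      msg <- c(msg, sprintf("%s values must lie in [0, 1]", s))
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulation configuration for the two-study generative model
#'
#' Describes the two-way gene x study model used to emulate a pair of
#' replicate two-group microarray studies:
#' \deqn{x_{gijk} = \mu + \alpha_g + \beta_i + (\alpha\beta)_{gi} +
#'   [\delta + \gamma_g + (\gamma\beta)_{gi}] I(k = 2) + \epsilon_{gijk}}
#' where \eqn{\alpha_g} is the gene main effect (shared across studies),
#' \eqn{\beta_i} a fixed study effect, \eqn{(\alpha\beta)_{gi}} a
#' gene-by-study interaction, and for truly differential genes the group
#' difference is \eqn{\delta + \gamma_g + (\gamma\beta)_{gi}} with the
#' shared effect \eqn{\gamma_g} drawn from
#' \eqn{N(\pm\mu_\gamma, sd_\gamma^2)} according to the gene's direction.
#' Defaults reproduce the study conditions of the simulation experiments:
#' 5000 genes, 10 samples per group, \eqn{\mu = 0}, \eqn{\alpha_g \sim
#' N(0,1)}, \eqn{\beta_i = 0.1}, interaction and residual standard
#' deviations 0.5, \eqn{\delta = 0}, \eqn{\gamma_g \sim N(\pm 2, 0.5^2)}.
#'
#' @slot nGenes number of genes G (default 5000).
#' @slot nPerGroup samples per group in each study (default 10).
#' @slot propReproducible proportion \eqn{\gamma} of genes that are truly
#'   differential in both studies.
#' @slot propUp split of differential genes assigned the up direction
#'   (default 0.5).
#' @slot mu overall mean (default 0).
#' @slot sdAlpha sd of the gene main effect (default 1).
#' @slot beta fixed study main effect, applied to both studies
#'   (default 0.1).
#' @slot sdAB sd of the gene-study interaction (default 0.5).
#' @slot delta fixed group-difference effect (default 0).
#' @slot muGamma absolute mean of the shared differential effect
#'   (default 2).
#' @slot sdGamma sd of the shared differential effect (default 0.5).
#' @slot sdGB sd of the gene-study interaction on the group difference
#'   (default 0.5).
#' @slot sdEps residual sd (default 0.5).
#' @slot seed integer seed used by [simulateStudies()].
#' @seealso [simulationConfig()], [simulateStudies()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nGenes = "integer", nPerGroup = "integer",
                 propReproducible = "numeric", propUp = "numeric",
                 mu = "numeric", sdAlpha = "numeric", beta = "numeric",
                 sdAB = "numeric", delta = "numeric", muGamma = "numeric",
                 sdGamma = "numeric", sdGB = "numeric", sdEps = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  for (s in c("propReproducible", "propUp")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
  }
  for (s in c("sdAlpha", "sdAB", "sdGamma", "sdGB", "sdEps"))
    if (slot(object, s) <= 0) msg <- c(msg, sprintf("%s must be > 0", s))
  if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationConfig-class
#' @param nGenes,nPerGroup,propReproducible,propUp,mu,sdAlpha,beta,sdAB
#'   see slots.
#' @param delta,muGamma,sdGamma,sdGB,sdEps,seed see slots.
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nGenes = 5000L, nPerGroup = 10L,
                             propReproducible = 0.8, propUp = 0.5,
                             mu = 0, sdAlpha = 1, beta = 0.1, sdAB = 0.5,
                             delta = 0, muGamma = 2, sdGamma = 0.5,
                             sdGB = 0.5, sdEps = 0.5, seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nPerGroup = as.integer(nPerGroup),
      propReproducible = propReproducible, propUp = propUp, mu = mu,
      sdAlpha = sdAlpha, beta = beta, sdAB = sdAB, delta = delta,
      muGamma = muGamma, sdGamma = sdGamma, sdGB = sdGB, sdEps = sdEps,
      seed = as.integer(seed))
}
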