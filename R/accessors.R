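#' Gene identifiers
#'
#' @param x a `TestStatTable`, `PosteriorTable` or `PValuePair`.
#' @return Character vector of gene ids.
#' @rdname geneIds
#' @export
setMethod("geneIds", "TestStatTable", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "PosteriorTable", function(x) x@geneIds)

#' @rdname geneIds
#' @export
setMethod("geneIds", "PValuePair", function(x) x@geneIds)

#' @describeIn TestStatTable-class number of genes.
#' @param x a `TestStatTable`.
#' @export
setMethod("length", "TestStatTable", function(x) length(x@geneIds))

#' Statistic accessors
#'
#' `stat1()`/`stat2()` return the per-gene statistics of study 1/study 2,
#' named by gene id.
#' @param x a `TestStatTable`.
#' @return Named numeric vector.
#' @export
stat1 <- function(x) setNames(x@d1, x@geneIds)

#' @rdname stat1
#' @export
stat2 <- function(x) setNames(x@d2, x@geneIds)

#' @describeIn TestStatTable-class coerce to data.frame with columns
#'   `gene_id`, `d1`, `d2`.
#' @param row.names,optional,... passed on conventions of the generic;
#'   ignored.
#' @export
setMethod("as.data.frame", "TestStatTable",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(gene_id = x@geneIds, d1 = x@d1, d2 = x@d2,
               stringsAsFactors = FALSE)
  })

#' @describeIn TestStatTable-class subset by index, logical mask or
#'   gene id.
#' @param i index vector.
#' @param j,drop ignored.
#' @export
setMethod("[", "TestStatTable", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    idx <- match(i, x@geneIds)
    if (anyNA(idx))
      stop("unknown gene id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  TestStatTable(x@geneIds[i], x@d1[i], x@d2[i])
})

#' Posterior probability matrix
#'
#' @param x a `PosteriorTable`.
#' @return Genes x 3 matrix with columns `p0`, `p1`, `p2`.
#' @export
posteriorProb <- function(x) {
  stopifnot(is(x, "PosteriorTable"))
  m <- x@prob
  rownames(m) <- x@geneIds
  m
}

#' Posterior null probability (local false discovery rate)
#'
#' @param x a `PosteriorTable`.
#' @return Named numeric vector of `p0` per gene.
#' @export
posteriorNull <- function(x) {
  stopifnot(is(x, "PosteriorTable"))
  setNames(x@prob[, 1L], x@geneIds)
}

#' @describeIn PosteriorTable-class number of genes.
#' @param x a `PosteriorTable`.
#' @export
setMethod("length", "PosteriorTable", function(x) length(x@geneIds))

#' Mixture weights of a fitted or specified model
#'
#' @param x a `MixtureParams` or `EMFit`.
#' @return Numeric(3): weights of the null, up and down components.
#' @export
mixtureWeights <- function(x) {
  if (is(x, "EMFit")) x <- x@params
  stopifnot(is(x, "MixtureParams"))
  setNames(x@pi, c("null", "up", "down"))
}

#' Component means
#'
#' @param x a `MixtureParams` or `EMFit`.
#' @return List of the three component means (the null mean is fixed at
#'   the origin).
#' @export
componentMeans <- function(x) {
  if (is(x, "EMFit")) x <- x@params
  stopifnot(is(x, "MixtureParams"))
  list(null = c(0, 0), up = x@mu1, down = x@mu2)
}

#' Fitted parameters of an EM fit
#'
#' @param fit an `EMFit`.
#' @return The [MixtureParams-class] of the winning restart.
#' @export
fittedParams <- function(fit) {
  stopifnot(is(fit, "EMFit"))
  fit@params
}

#' Log-likelihood trace of an EM fit
#'
#' @param fit an `EMFit`.
#' @return Numeric vector, the log-likelihood at the parameters entering
#'   each iteration of the winning restart (final entry: at the returned
#'   parameters).
#' @export
loglikTrace <- function(fit) {
  stopifnot(is(fit, "EMFit"))
  fit@loglikTrace
}

#' Study group labels
#'
#' @param study an `ExpressionStudy`.
#' @return Integer vector of per-sample labels (1 control, 2 treatment).
#' @export
studyGroups <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  SummarizedExperiment::colData(study)$group
}

#' Study identifier
#'
#' @param study an `ExpressionStudy`.
#' @export
studyId <- function(study) {
  stopifnot(is(study, "ExpressionStudy"))
  S4Vectors::metadata(study)$studyId
}
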