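#' @rdname geneIds
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname tStatistics
#' @export
setGeneric("tStatistics", function(study, ...) standardGeneric("tStatistics"))

#' @rdname posteriorProbabilities
#' @export
setGeneric("posteriorProbabilities",
  function(stats, params) standardGeneric("posteriorProbabilities"))

#' @rdname logLikelihood
#' @export
setGeneric("logLikelihood",
  function(stats, params) standardGeneric("logLikelihood"))
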