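#' Per-gene two-sample t statistics
#'
#' Computes, for each gene, the unpaired pooled-variance t statistic of
#' treatment (group 2) versus control (group 1):
#' \deqn{d_g = (\bar x_{g2} - \bar x_{g1}) / s_g, \quad
#'   s_g^2 = (1/n_1 + 1/n_2) \frac{SS_{g1} + SS_{g2}}{n_1 + n_2 - 2}}
#' where \eqn{SS_{gk}} is the within-group sum of squared deviations. The
#' sign convention is treatment minus control: positive means
#' up-regulated under treatment.
#'
#' Genes with zero pooled variance have no defined statistic; by default
#' they raise an error naming the gene. With `dropDegenerate = TRUE` they
#' are dropped with a message instead.
#'
#' @param study an [ExpressionStudy-class].
#' @param dropDegenerate drop zero-variance genes instead of erroring.
#' @param ... unused.
#' @return Named numeric vector of t statistics (one per retained gene).
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- paste0("s", 1:6)
#' tStatistics(ExpressionStudy(m, group = c(1, 1, 1, 2, 2, 2)))
#' @rdname tStatistics
#' @export
setMethod("tStatistics", "ExpressionStudy",
  function(study, dropDegenerate = FALSE, ...) {
    validObject(study)
    x <- SummarizedExperiment::assay(study, "exprs")
    grp <- studyGroups(study)
    x1 <- x[, grp == 1L, drop = FALSE]
    x2 <- x[, grp == 2L, drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss1 <- rowSums((x1 - m1)^2)
    ss2 <- rowSums((x2 - m2)^2)
    s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
    bad <- s == 0
    if (any(bad)) {
      if (!dropDegenerate)
        stop("zero pooled variance for gene(s): ",
             paste(utils::head(rownames(x)[bad], 5L), collapse = ", "),
             if (sum(bad) > 5L) sprintf(" (and %d more)", sum(bad) - 5L))
      message(sum(bad), " zero-variance gene(s) dropped")
    }
    d <- (m2 - m1) / s
    d[!bad]
  })

#' Pair two studies' statistics on their common genes
#'
#' Inner-joins two per-study statistic vectors on gene id, in the order of
#' the first study. Genes present in only one study are dropped; a
#' message reports how many were dropped from each side. This mirrors the
#' common-gene restriction applied when comparing two array platforms.
#'
#' @param stats1,stats2 numeric statistic vectors, named by gene id (as
#'   returned by [tStatistics()]); alternatively supply `ids1`/`ids2`.
#' @param ids1,ids2 gene identifiers; default to the vector names.
#' @return A [TestStatTable-class] on the common genes.
#' @examples
#' pairStudies(c(a = 1, b = 2, c = 3), c(b = 0.5, c = -1, d = 2))
#' @export
pairStudies <- function(stats1, stats2, ids1 = names(stats1),
                        ids2 = names(stats2)) {
  if (is.null(ids1) || is.null(ids2))
    stop("gene ids are required (names or ids1=/ids2=)")
  if (anyDuplicated(ids1))
    stop("duplicated gene id(s) in study 1: ",
         paste(unique(ids1[duplicated(ids1)]), collapse = ", "))
  if (anyDuplicated(ids2))
    stop("duplicated gene id(s) in study 2: ",
         paste(unique(ids2[duplicated(ids2)]), collapse = ", "))
  common <- ids1[ids1 %in% ids2]
  if (length(common) == 0L)
    stop("no genes in common between the two studies")
  drop1 <- length(ids1) - length(common)
  drop2 <- length(ids2) - length(common)
  if (drop1 + drop2 > 0L)
    message(sprintf(
      "pairing on %d common genes; %d dropped (%d from study 1, %d from study 2)",
      length(common), drop1 + drop2, drop1, drop2))
  TestStatTable(common,
                as.numeric(stats1)[match(common, ids1)],
                as.numeric(stats2)[match(common, ids2)])
}
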