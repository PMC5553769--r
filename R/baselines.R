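#' Two-sided p-values for each study's statistics
#'
#' Converts the paired statistics to per-study two-sided p-values,
#' `p = 2 * (1 - F(|d|))`, under a t reference with the given degrees of
#' freedom (`df = Inf` uses the standard normal). For a two-group design
#' the natural choice is `df = n1 + n2 - 2`.
#'
#' @param stats a [TestStatTable-class].
#' @param df1,df2 degrees of freedom of the reference distribution for
#'   study 1 and study 2; `Inf` for the normal.
#' @return A [PValuePair-class] carrying the p-values and statistic signs.
#' @export
twoSidedP <- function(stats, df1, df2) {
  stopifnot(is(stats, "TestStatTable"))
  for (df in c(df1, df2))
    if (!is.numeric(df) || length(df) != 1L || is.na(df) || df < 1)
      stop("degrees of freedom must be >= 1 (or Inf for the normal)")
  pOne <- function(d, df) {
    if (is.infinite(df)) 2 * stats::pnorm(-abs(d))
    else 2 * stats::pt(-abs(d), df = df)
  }
  new("PValuePair", geneIds = stats@geneIds,
      p1 = pOne(stats@d1, df1), p2 = pOne(stats@d2, df2),
      sign1 = sign(stats@d1), sign2 = sign(stats@d2))
}

#' Max-p partial-conjunction reproducibility calls
#'
#' The partial-conjunction test of "significant in all studies" reduces,
#' for two studies, to comparing the larger of the two p-values with the
#' level: a gene is called reproducible when `max(p1, p2) < alpha`. By
#' construction the rule ignores the statistics' signs, so genes
#' significant in both studies but moving in opposite directions are
#' still called; [signDiscordant()] exposes them. Under independent null
#' p-values the false-call rate of the raw rule is about `alpha^2`.
#'
#' `adjust = "BH"` applies a Benjamini-Hochberg adjustment to the max-p
#' values before thresholding, for users who want FDR-style control
#' rather than the raw per-gene rule.
#'
#' @param p a [PValuePair-class].
#' @param alpha significance level in (0, 1).
#' @param adjust `"none"` (raw max-p, the default) or `"BH"`.
#' @return data.frame with columns `gene_id`, `p1`, `p2`, `p_max`
#'   (adjusted if requested), `call`, `direction` (`"up"`/`"down"` when
#'   both statistics' signs agree and the gene is called, else
#'   `"none"`).
#' @export
partialConjunction <- function(p, alpha, adjust = c("none", "BH")) {
  stopifnot(is(p, "PValuePair"))
  adjust <- match.arg(adjust)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value strictly between 0 and 1")
  pmaxv <- pmax(p@p1, p@p2)
  if (adjust == "BH")
    pmaxv <- stats::p.adjust(pmaxv, method = "BH")
  call <- pmaxv < alpha
  agree <- p@sign1 == p@sign2 & p@sign1 != 0
  direction <- ifelse(call & agree,
                      ifelse(p@sign1 > 0, "up", "down"), "none")
  data.frame(gene_id = p@geneIds, p1 = p@p1, p2 = p@p2, p_max = pmaxv,
             call = call, direction = direction, stringsAsFactors = FALSE)
}

#' Rank genes by the max-p criterion
#'
#' Comparator ranking used for "top k" selections with the
#' partial-conjunction baseline: ascending `max(p1, p2)`, ties broken by
#' gene id.
#'
#' @param p a [PValuePair-class].
#' @param k number of genes to return.
#' @return Character vector of `k` gene ids.
#' @export
topGenesMaxP <- function(p, k) {
  stopifnot(is(p, "PValuePair"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k > length(p@geneIds))
    stop("k must be a positive integer no larger than the number of genes")
  ord <- order(pmax(p@p1, p@p2), p@geneIds)
  p@geneIds[ord[seq_len(as.integer(k))]]
}
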