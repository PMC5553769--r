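#' Classify genes as reproducible by posterior null probability
#'
#' A gene is called reproducible when its posterior null probability
#' (local false discovery rate) satisfies `p0 < alpha` (strict
#' inequality). Called genes get a direction from the larger of the up
#' and down posteriors; uncalled genes get direction `"none"`.
#'
#' @param post a [PosteriorTable-class].
#' @param alpha significance level in (0, 1).
#' @param stats optional [TestStatTable-class]; if supplied, `d1`/`d2`
#'   columns are included in the output.
#' @return data.frame with columns `gene_id`, (`d1`, `d2`,) `p0`, `p1`,
#'   `p2`, `call` (logical), `direction` (`"up"`, `"down"`, `"none"`).
#' @export
classifyGenes <- function(post, alpha, stats = NULL) {
  stopifnot(is(post, "PosteriorTable"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value strictly between 0 and 1")
  P <- post@prob
  call <- P[, 1L] < alpha
  direction <- ifelse(call, ifelse(P[, 2L] >= P[, 3L], "up", "down"), "none")
  out <- data.frame(gene_id = post@geneIds, p0 = P[, 1L], p1 = P[, 2L],
                    p2 = P[, 3L], call = call, direction = direction,
                    stringsAsFactors = FALSE)
  if (!is.null(stats)) {
    stopifnot(is(stats, "TestStatTable"))
    idx <- match(out$gene_id, stats@geneIds)
    if (anyNA(idx))
      stop("posterior table contains genes absent from the statistics table")
    out <- cbind(out[1L], d1 = stats@d1[idx], d2 = stats@d2[idx],
                 out[-1L])
  }
  rownames(out) <- NULL
  out
}

#' Top-k genes by reproducibility score
#'
#' Ranks genes by ascending posterior null probability `p0`. Ties are
#' broken by descending `max(p1, p2)` and then by gene id, making the
#' ranking fully deterministic.
#'
#' @param post a [PosteriorTable-class].
#' @param k number of genes to return, `1 <= k <= length(post)`.
#' @return Character vector of `k` gene ids, best first.
#' @export
topGenes <- function(post, k) {
  stopifnot(is(post, "PosteriorTable"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("k must be a positive integer")
  if (k > length(post))
    stop("k exceeds the number of genes (", length(post), ")")
  P <- post@prob
  ord <- order(P[, 1L], -pmax(P[, 2L], P[, 3L]), post@geneIds)
  post@geneIds[ord[seq_len(as.integer(k))]]
}

#' Sign-discordant genes among a selection
#'
#' Returns the subset of `selected` genes whose statistics have opposite
#' signs in the two studies (`d1 * d2 < 0`) — genes that may look
#' significant in both studies yet move in opposite directions, the
#' failure mode that p-value-only reproducibility rules cannot see. A
#' zero statistic is counted as concordant.
#'
#' @param stats a [TestStatTable-class].
#' @param selected character vector of gene ids, a subset of
#'   `geneIds(stats)`; defaults to all genes.
#' @return Character vector of discordant gene ids (a subset of
#'   `selected`, in its order).
#' @examples
#' tab <- TestStatTable(c("a", "b"), c(3.3, 2.0), c(-3.6, 2.1))
#' signDiscordant(tab)  # "a"
#' @export
signDiscordant <- function(stats, selected = geneIds(stats)) {
  stopifnot(is(stats, "TestStatTable"))
  idx <- match(selected, stats@geneIds)
  if (anyNA(idx))
    stop("unknown gene id(s): ",
         paste(selected[is.na(idx)], collapse = ", "))
  selected[stats@d1[idx] * stats@d2[idx] < 0]
}
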