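#' Simulate a pair of replicate two-group studies
#'
#' Draws expression data for two studies under the gene-by-study model of
#' [SimulationConfig-class]. The gene main effect \eqn{\alpha_g} and the
#' differential effect \eqn{\gamma_g} are drawn once and shared by both
#' studies; the interactions \eqn{(\alpha\beta)_{gi}} and
#' \eqn{(\gamma\beta)_{gi}} are drawn per gene and study; residuals per
#' observation. Exactly `round(nGenes * propReproducible)` genes are
#' truly differential, of which `round(. * propUp)` are up-regulated
#' (positive \eqn{\gamma_g} mean) and the rest down-regulated. Genes are
#' assigned to blocks by index; all randomness is in the drawn effects.
#' Fully deterministic given the seed.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed` when supplied.
#' @return List with elements `study1`, `study2`
#'   ([ExpressionStudy-class]) and `truth`, a data.frame with columns
#'   `gene_id`, `differential` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @examples
#' sim <- simulateStudies(simulationConfig(nGenes = 50, seed = 1))
#' table(sim$truth$direction)
#' @export
simulateStudies <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  G <- config@nGenes
  n <- config@nPerGroup
  nDiff <- round(G * config@propReproducible)
  nUp <- round(nDiff * config@propUp)
  direction <- rep("none", G)
  if (nDiff > 0L) {
    direction[seq_len(nDiff)] <- c(rep("up", nUp), rep("down", nDiff - nUp))
  }
  geneIds <- sprintf("g%05d", seq_len(G))
  .withSeed(seed, {
    alpha <- rnorm(G, 0, config@sdAlpha)
    gammaG <- numeric(G)
    if (nDiff > 0L) {
      sgn <- ifelse(direction[seq_len(nDiff)] == "up", 1, -1)
      gammaG[seq_len(nDiff)] <- sgn * rnorm(nDiff, config@muGamma,
                                            config@sdGamma)
    }
    studies <- lapply(1:2, function(i) {
      ab <- rnorm(G, 0, config@sdAB)
      gb <- numeric(G)
      if (nDiff > 0L)
        gb[seq_len(nDiff)] <- rnorm(nDiff, 0, config@sdGB)
      base <- config@mu + alpha + config@beta + ab
      diff <- ifelse(direction == "none", 0,
                     config@delta + gammaG + gb)
      x <- matrix(rnorm(G * 2L * n, 0, config@sdEps), nrow = G)
      x <- x + base
      x[, (n + 1L):(2L * n)] <- x[, (n + 1L):(2L * n)] + diff
      colnames(x) <- sprintf("s%d_%02d", i, seq_len(2L * n))
      ExpressionStudy(x, group = rep(c(1L, 2L), each = n),
                      geneIds = geneIds, studyId = paste0("study", i))
    })
    list(study1 = studies[[1L]], study2 = studies[[2L]],
         truth = data.frame(gene_id = geneIds,
                            differential = direction != "none",
                            direction = direction,
                            stringsAsFactors = FALSE))
  })
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML mapping whose keys mirror the arguments of
#' [simulationConfig()] (e.g. `nGenes`, `propReproducible`, `sdEps`,
#' `seed`); omitted keys keep their defaults. Unknown keys raise an
#' error.
#'
#' @param path path to a YAML file.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  obj <- yaml::read_yaml(path)
  known <- names(formals(simulationConfig))
  bad <- setdiff(names(obj), known)
  if (length(bad))
    stop("unknown configuration key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(simulationConfig, obj)
}

#' Score reproducibility calls against generative truth
#'
#' Computes sensitivity (truly differential genes called), specificity
#' (truly null genes not called) and the misclassification rate
#' `(FP + FN) / G`. A call counts as a true positive whenever the gene is
#' truly differential, regardless of the called direction; direction
#' agreement among true positives is reported separately as
#' `direction_accuracy`.
#'
#' @param calls data.frame with columns `gene_id`, `call` and optionally
#'   `direction`, as returned by [classifyGenes()] or
#'   [partialConjunction()].
#' @param truth data.frame with columns `gene_id`, `differential`,
#'   `direction`, as returned by [simulateStudies()].
#' @return One-row data.frame with columns `sensitivity` (NA when no
#'   gene is truly differential), `specificity` (NA when none is null),
#'   `misclassification`, `direction_accuracy`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluateCalls <- function(calls, truth) {
  stopifnot(is.data.frame(calls), is.data.frame(truth),
            all(c("gene_id", "call") %in% names(calls)),
            all(c("gene_id", "differential") %in% names(truth)))
  idx <- match(calls$gene_id, truth$gene_id)
  if (anyNA(idx) || length(calls$gene_id) != nrow(truth))
    stop("calls and truth must cover the same gene set")
  truth <- truth[idx, , drop = FALSE]
  G <- nrow(truth)
  tp <- sum(calls$call & truth$differential)
  fp <- sum(calls$call & !truth$differential)
  fn <- sum(!calls$call & truth$differential)
  tn <- sum(!calls$call & !truth$differential)
  nTrue <- tp + fn
  nNull <- fp + tn
  dirAcc <- if (tp > 0L && "direction" %in% names(calls)) {
    hit <- calls$call & truth$differential
    mean(calls$direction[hit] == truth$direction[hit])
  } else NA_real_
  data.frame(sensitivity = if (nTrue > 0L) tp / nTrue else NA_real_,
             specificity = if (nNull > 0L) tn / nNull else NA_real_,
             misclassification = (fp + fn) / G,
             direction_accuracy = dirAcc,
             tp = tp, fp = fp, tn = tn, fn = fn)
}

# One simulation replicate: generate data, compute per-study t
# statistics, pair them, and apply the requested methods.
.simReplicate <- function(config, alpha, repSeed, methods, em) {
  sim <- simulateStudies(config, seed = repSeed)
  d1 <- tStatistics(sim$study1)
  d2 <- tStatistics(sim$study2)
  stats <- pairStudies(d1, d2)
  df <- 2L * config@nPerGroup - 2L
  out <- list()
  for (m in methods) {
    calls <- if (m == "proposed") {
      cfg <- emControl(nStarts = em@nStarts, maxIter = em@maxIter,
                       tolParam = em@tolParam, tolLoglik = em@tolLoglik,
                       seed = .deriveSeed(repSeed, 1L, salt = 37),
                       minVar = em@minVar)
      fit <- emFit(stats, cfg)
      classifyGenes(posteriorProbabilities(stats, fittedParams(fit)), alpha)
    } else {
      partialConjunction(twoSidedP(stats, df, df), alpha)
    }
    out[[m]] <- evaluateCalls(calls, sim$truth)
  }
  out
}

#' Run the simulation study
#'
#' Repeats, `nReps` times: simulate a pair of studies, compute per-study
#' t statistics, pair them on the common genes, apply each requested
#' method (the mixture-EM classifier and/or the max-p baseline) at level
#' `alpha`, and score the calls against the generative truth. Replicate
#' seeds are derived deterministically from `seed`. A replicate in which
#' every EM restart collapses is re-drawn with a fresh, logged seed (at
#' most 3 retries) — both methods see the same data within a replicate.
#'
#' @param config a [SimulationConfig-class] describing one replicate.
#' @param alpha significance level for the reproducibility calls.
#' @param nReps number of replicates.
#' @param seed master seed for the whole study.
#' @param methods any of `"proposed"` (mixture EM) and `"bh"` (max-p
#'   partial conjunction).
#' @param em an [EMConfig-class] supplying the EM settings (its seed slot
#'   is ignored; per-replicate seeds are derived from `seed`).
#' @return List with `perRep` (data.frame: one row per replicate and
#'   method with the metrics of [evaluateCalls()]) and `summary`
#'   (data.frame: per method and metric, mean and standard error across
#'   replicates; the SE is NA when `nReps == 1`).
#' @examples
#' \donttest{
#' cfg <- simulationConfig(nGenes = 400, propReproducible = 0.5)
#' runSimulationStudy(cfg, alpha = 0.1, nReps = 2, seed = 1,
#'                    em = emControl(nStarts = 3))
#' }
#' @export
runSimulationStudy <- function(config, alpha, nReps, seed,
                               methods = c("proposed", "bh"),
                               em = emControl()) {
  stopifnot(is(config, "SimulationConfig"), nReps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(nReps)) {
    repSeed <- .deriveSeed(seed, r)
    res <- NULL
    for (attempt in 0:3) {
      usedSeed <- if (attempt == 0L) repSeed
                  else .deriveSeed(repSeed, attempt, salt = 997)
      if (attempt > 0L)
        message(sprintf("replicate %d: EM failed, redrawing with seed %d",
                        r, usedSeed))
      res <- tryCatch(
        .simReplicate(config, alpha, usedSeed, methods, em),
        error = function(e) {
          if (grepl("collapsed", conditionMessage(e)) && attempt < 3L) NULL
          else stop(e)
        })
      if (!is.null(res)) break
    }
    if (is.null(res))
      stop("replicate ", r, " failed after 3 redraws")
    for (m in methods)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(rep = r, method = m, seed = usedSeed), res[[m]])
  }
  perRep <- do.call(rbind, rows)
  metrics <- c("sensitivity", "specificity", "misclassification",
               "direction_accuracy")
  summary <- do.call(rbind, lapply(methods, function(m) {
    sub <- perRep[perRep$method == m, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(k) {
      v <- sub[[k]]
      data.frame(method = m, metric = k, mean = mean(v, na.rm = TRUE),
                 se = if (nrow(sub) > 1L)
                        sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
                      else NA_real_)
    }))
  }))
  rownames(summary) <- NULL
  list(perRep = perRep, summary = summary)
}
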