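# Tab-separated readers and writers. Plain TSV is the interchange format:
# the tool meets users at the statistics / expression-table level, after
# platform-specific preprocessing has been done elsewhere.

.readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

.checkNumericColumn <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v) || anyNA(suppressWarnings(as.numeric(v)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))
    stop(sprintf("non-numeric value in column '%s' of %s (line %s)",
                 col, path, paste(utils::head(bad + 1L, 5L), collapse = ", ")))
  }
  as.numeric(v)
}

#' Read a paired test-statistic table
#'
#' Reads a TSV with header columns `gene_id`, `d1`, `d2`. Extra columns
#' are ignored with a warning. Malformed files (missing columns,
#' non-numeric entries with their line numbers, duplicated ids) raise
#' descriptive errors.
#'
#' @param path path to a TSV file.
#' @return A [TestStatTable-class].
#' @seealso [writeStatsTsv()]
#' @export
readStatsTsv <- function(path) {
  df <- .readTsv(path)
  need <- c("gene_id", "d1", "d2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring extra column(s) in ", path, ": ",
            paste(extra, collapse = ", "))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    lines <- which(df$gene_id %in% dup) + 1L
    stop(sprintf("duplicated gene id(s) in %s: %s (lines %s)", path,
                 paste(dup, collapse = ", "),
                 paste(utils::head(lines, 10L), collapse = ", ")))
  }
  TestStatTable(df$gene_id,
                .checkNumericColumn(df, "d1", path),
                .checkNumericColumn(df, "d2", path))
}

#' Write a paired test-statistic table
#'
#' @param stats a [TestStatTable-class].
#' @param path output path. Numbers are written locale-independently with
#'   a "." decimal separator at full double precision, so
#'   [readStatsTsv()] round-trips exactly.
#' @return `path`, invisibly.
#' @export
writeStatsTsv <- function(stats, path) {
  stopifnot(is(stats, "TestStatTable"))
  df <- data.frame(gene_id = stats@geneIds,
                   d1 = sprintf("%.17g", stats@d1),
                   d2 = sprintf("%.17g", stats@d2))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix TSV has a first column of gene ids and one column per
#' sample; the metadata TSV has columns `sample_id` and `group` (1 =
#' control, 2 = treatment). Columns are matched to metadata rows by
#' sample id, so column order is irrelevant.
#'
#' @param pathMatrix path to the expression TSV.
#' @param pathMeta path to the sample-metadata TSV.
#' @param studyId identifier for the resulting study.
#' @return An [ExpressionStudy-class].
#' @export
readExpression <- function(pathMatrix, pathMeta, studyId = pathMatrix) {
  df <- .readTsv(pathMatrix)
  if (ncol(df) < 2L) stop("expression file needs gene ids plus samples")
  geneIds <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop("non-numeric expression values in ", pathMatrix)
  rownames(mat) <- geneIds
  meta <- .readTsv(pathMeta)
  need <- c("sample_id", "group")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns sample_id and group: ", pathMeta)
  if (!all(meta$group %in% c(1L, 2L)))
    stop("group labels must be 1 or 2 in ", pathMeta)
  idx <- match(colnames(mat), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  ExpressionStudy(mat, group = meta$group[idx], studyId = studyId)
}

#' Serialize fitted mixture parameters as JSON
#'
#' Writes the parameter set (and, when given an [EMFit-class], the final
#' log-likelihood, iteration count and convergence flag) in a stable JSON
#' layout with keys `pi`, `mu1`, `mu2`, `sigma_g2`, `sigma_G1_2`,
#' `sigma_G2_2`, `loglik`, `n_iter`, `converged`.
#'
#' @param fit an [EMFit-class] or bare [MixtureParams-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readMixtureParams()]
#' @export
writeMixtureParams <- function(fit, path) {
  if (is(fit, "EMFit")) {
    params <- fit@params
    extra <- list(loglik = fit@loglik, n_iter = fit@nIter,
                  converged = fit@converged)
  } else {
    stopifnot(is(fit, "MixtureParams"))
    params <- fit
    extra <- list(loglik = NA_real_, n_iter = NA_integer_, converged = NA)
  }
  obj <- c(list(pi = params@pi, mu1 = params@mu1, mu2 = params@mu2,
                sigma_g2 = params@sigmaSq, sigma_G1_2 = params@sigmaSqG1,
                sigma_G2_2 = params@sigmaSqG2), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read mixture parameters from JSON
#'
#' @param path path written by [writeMixtureParams()].
#' @return A [MixtureParams-class]; the stored `loglik`, `n_iter` and
#'   `converged` entries are attached as an attribute `"fitInfo"`.
#' @export
readMixtureParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pi", "mu1", "mu2", "sigma_g2", "sigma_G1_2", "sigma_G2_2")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("missing field(s) in ", path, ": ", paste(miss, collapse = ", "))
  params <- MixtureParams(obj$pi, obj$mu1, obj$mu2, obj$sigma_g2,
                          obj$sigma_G1_2, obj$sigma_G2_2)
  attr(params, "fitInfo") <- obj[intersect(
    c("loglik", "n_iter", "converged"), names(obj))]
  params
}

#' Write a run manifest
#'
#' Records a command invocation — name, parameters, seed, timestamp,
#' package version and MD5 checksums of the input files — so a run can be
#' audited and reproduced.
#'
#' @param path output JSON path.
#' @param command command name.
#' @param parameters named list of parameter values.
#' @param seed integer seed used.
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, command, parameters = list(),
                             seed = NA_integer_, inputs = character()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(command = command, parameters = parameters, seed = seed,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version =
                as.character(utils::packageVersion("repmix")),
              input_md5 = sums)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Packaged sign-discordance example tables
#'
#' Returns two small statistic tables derived from a published pair of
#' idiopathic pulmonary fibrosis microarray studies (GEO series GSE28042
#' and GSE33566, blood expression in IPF patients versus healthy
#' controls): genes that p-value-based reproducibility rules placed among
#' the top selections even though their t statistics have opposite signs
#' in the two studies. `maxp` holds the 23 genes flagged from a max-p
#' partial-conjunction selection, `copula` the 7 genes flagged from a
#' copula-mixture selection. They exercise [signDiscordant()] and
#' illustrate the failure mode the mixture model is designed to avoid.
#'
#' @return Named list of two [TestStatTable-class] objects (`maxp`,
#'   `copula`).
#' @examples
#' length(discordantGeneTables()$maxp)  # 23
#' @export
discordantGeneTables <- function() {
  rd <- function(f) readStatsTsv(
    system.file("extdata", f, package = "repmix", mustWork = TRUE))
  list(maxp = rd("ipf_discordant_maxp.tsv"),
       copula = rd("ipf_discordant_copula.tsv"))
}
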