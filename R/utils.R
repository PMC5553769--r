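# Internal numeric and RNG helpers.

# Row-wise log-sum-exp of a matrix of log terms. Columns with weight zero
# arrive as -Inf and contribute exactly 0 after exponentiation.
.rowLogSumExp <- function(lw) {
  mx <- do.call(pmax, lapply(seq_len(ncol(lw)), function(j) lw[, j]))
  if (any(!is.finite(mx)))
    stop("all mixture terms vanished for at least one observation")
  mx + log(rowSums(exp(lw - mx)))
}

# Deterministic 31-bit sub-seed derived from a master seed and a stream
# index, so every restart/replicate has its own reproducible stream.
.deriveSeed <- function(seed, stream, salt = 0) {
  s <- (as.double(seed) %% 2147483647) * 1009 +
    as.double(stream) * 7919 + as.double(salt) * 104729
  as.integer(s %% 2147483629 + 1)
}

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Flat parameter vector used for the delta1 stopping rule and restart
# bookkeeping.
.paramVector <- function(params) {
  c(params@pi, params@mu1, params@mu2, params@sigmaSq,
    params@sigmaSqG1, params@sigmaSqG2)
}

.condWrap <- function(class, msg, call = NULL) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = call))
}
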