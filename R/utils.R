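# internal helpers shared across modules

# Evaluate expr with a local RNG state seeded by `seed`; NULL leaves the
# global stream untouched. Seeds are explicit arguments throughout the
# package, never hidden global state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Smoothed permutation p-value; guarantees p >= 1/(n+1), never 0.
.permP <- function(nullStats, obsStat) {
  (1 + sum(nullStats >= obsStat)) / (length(nullStats) + 1)
}

.caseIdx <- function(ds) which(sampleGroups(ds) == "case")
.controlIdx <- function(ds) which(sampleGroups(ds) == "control")

.checkGroups <- function(ds, minPer = 1L) {
  nc <- length(.caseIdx(ds)); nr <- length(.controlIdx(ds))
  if (nc < minPer || nr < minPer)
    stop(sprintf("need at least %d case and %d control samples (have %d/%d)",
                 minPer, minPer, nc, nr))
  invisible(TRUE)
}

# Row-wise group means/variances for a genes x samples matrix.
.rowGroupStats <- function(m, idx) {
  n <- length(idx)
  mu <- rowMeans(m[, idx, drop = FALSE])
  v <- if (n > 1)
    rowSums((m[, idx, drop = FALSE] - mu)^2) / (n - 1)
  else rep(NA_real_, nrow(m))
  list(mean = mu, var = v, n = n)
}
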