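# Structure-free scorers: jackknifed Fisher (EASE score) and GSEA.

#' Jackknifed Fisher exact (EASE score) tail probability
#'
#' The upper-tail hypergeometric probability of the DE-in-set count with
#' one hit removed (`k` replaced by `max(k - 1, 0)`), which penalises sets
#' whose significance hangs on a single possibly false-positive DE gene.
#' `k = 0` returns 1.
#'
#' @param k DE genes in the set (measured).
#' @param K measured set size.
#' @param nDe total DE genes in the background.
#' @param N background size.
#' @return numeric(1) probability; always >= the plain Fisher upper tail
#'   at `k`.
#' @export
easePvalue <- function(k, K, nDe, N) {
  if (k < 0 || k > min(K, nDe) || K > N || nDe > N)
    stop("inconsistent contingency counts")
  if (k == 0) return(1)
  phyper(max(k - 1, 0) - 1, nDe, N - nDe, K, lower.tail = FALSE)
}

#' Run the jackknifed Fisher test over a gene-set collection
#'
#' @param sets a [GeneSetCollection-class].
#' @param deGenes character vector of DE gene ids.
#' @param background measured gene universe.
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return data.frame with `pathway_id`, `method`, `score` (the DE-in-set
#'   count k), `p_value`, `fdr`, `significant`, `k`, `K`. Sets with no
#'   measured genes are skipped with a warning.
#' @export
runEase <- function(sets, deGenes, background, fdrThreshold = 0.05) {
  deGenes <- intersect(deGenes, background)
  rows <- lapply(names(sets), function(id) {
    g <- intersect(sets[[id]], background)
    if (!length(g)) {
      warning(sprintf("set '%s' has no measured genes; skipped", id))
      return(NULL)
    }
    k <- length(intersect(g, deGenes))
    data.frame(pathway_id = id, k = k, K = length(g),
               p_value = easePvalue(k, length(g), length(deGenes),
                                    length(background)))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no set had measured genes")
  res$method <- "DAVID"
  res$score <- res$k
  res$fdr <- bhFDR(res$p_value)
  res$significant <- res$fdr < fdrThreshold
  res[, c("pathway_id", "method", "score", "p_value", "fdr", "significant",
          "k", "K")]
}

#' Rank genes by signal-to-noise differential expression
#'
#' The ranking statistic is the signal-to-noise ratio
#' `d(i) = (mean_case - mean_control) / (sd_case + sd_control)`, with each
#' group's standard deviation floored at `0.2 * |group mean|` (the classic
#' stabilisation); genes whose denominator is 0 after flooring get
#' `d = 0`. Ties are broken by gene id (lexicographic), making the ranking
#' deterministic.
#'
#' @param ds an [ExpressionDataset-class] with both groups nonempty.
#' @return data.frame ordered by decreasing `d`: columns `gene`, `d`,
#'   `rank` (1-based).
#' @export
rankGenes <- function(ds) {
  .checkGroups(ds, minPer = 1L)
  d <- .snrStatistic(exprValues(ds), .caseIdx(ds), .controlIdx(ds))
  ord <- order(-d, names(d), method = "radix")
  data.frame(gene = names(d)[ord], d = unname(d[ord]),
             rank = seq_along(d), row.names = NULL)
}

.snrStatistic <- function(values, caseIdx, controlIdx) {
  a <- .rowGroupStats(values, caseIdx)
  b <- .rowGroupStats(values, controlIdx)
  sdA <- if (a$n > 1) sqrt(a$var) else rep(0, nrow(values))
  sdB <- if (b$n > 1) sqrt(b$var) else rep(0, nrow(values))
  den <- pmax(sdA, 0.2 * abs(a$mean)) + pmax(sdB, 0.2 * abs(b$mean))
  d <- ifelse(den > 0, (a$mean - b$mean) / den, 0)
  stats::setNames(d, rownames(values))
}

#' Running-sum enrichment score for one gene set
#'
#' Scans the ranked list once, accumulating at every rank the weighted hit
#' fraction `P_hit` (member genes weighted by `|d|^u`, normalised to 1)
#' and the uniform miss fraction `P_miss` (1/(n - p) per non-member), and
#' returns the maximum absolute gap `max_r |P_hit(r) - P_miss(r)|`,
#' evaluated after every rank. With `u = 0` only ranks matter; with
#' `u = 1` hits are weighted by their differential-expression magnitude.
#'
#' @param rankedList data.frame from [rankGenes()] (columns `gene`, `d`).
#' @param geneSet character vector of member gene ids.
#' @param u weight exponent (0 or 1; any non-negative real accepted).
#' @return numeric(1) enrichment score in \[0, 1\].
#' @export
enrichmentScore <- function(rankedList, geneSet, u = 1) {
  member <- rankedList$gene %in% geneSet
  .esScan(member, abs(rankedList$d), u)
}

.esScan <- function(member, absd, u) {
  n <- length(member)
  p <- sum(member)
  if (p == 0L || p == n)
    stop("gene set must hit some but not all ranked genes")
  w <- ifelse(member, absd^u, 0)
  tot <- sum(w)
  if (tot == 0) w[member] <- 1  # all-zero stats: fall back to equal weights
  hit <- cumsum(w) / sum(w)
  miss <- cumsum(!member) / (n - p)
  max(abs(hit - miss))
}

#' Gene set enrichment analysis with sample-label permutation
#'
#' Ranks all genes with [rankGenes()], scores each set with
#' [enrichmentScore()], and assesses significance by re-ranking under
#' uniformly drawn sample-label permutations (identity permutations are
#' not excluded): `p = (1 + #\{S_null >= S_obs\}) / (nPerm + 1)`. FDR by
#' [bhFDR()] across sets.
#'
#' @param ds an [ExpressionDataset-class] (conventionally unscaled input).
#' @param sets a [GeneSetCollection-class].
#' @param u weight exponent for [enrichmentScore()] (default 1).
#' @param nPerm label permutations (default 1000).
#' @param seed integer seed (or NULL).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return data.frame with `pathway_id`, `method`, `score` (S), `p_value`,
#'   `fdr`, `significant`, `n_genes`. Sets with no measured genes, or
#'   covering the whole universe, are skipped with a warning.
#' @export
runGsea <- function(ds, sets, u = 1, nPerm = 1000, seed = NULL,
                    fdrThreshold = 0.05) {
  .checkGroups(ds, minPer = 2L)
  X <- exprValues(ds)
  ci <- .caseIdx(ds)
  m <- ncol(X)
  usable <- Filter(function(id) {
    k <- length(intersect(sets[[id]], rownames(X)))
    ok <- k > 0L && k < nrow(X)
    if (!ok) warning(sprintf(
      "set '%s' hits none or all of the measured genes; skipped", id))
    ok
  }, names(sets))
  if (!length(usable)) stop("no usable gene set")
  memberOf <- lapply(usable, function(id) rownames(X) %in% sets[[id]])
  names(memberOf) <- usable
  scoreAll <- function(caseCols) {
    d <- .snrStatistic(X, caseCols, setdiff(seq_len(m), caseCols))
    ord <- order(-d, names(d), method = "radix")
    absd <- abs(d[ord])
    vapply(memberOf, function(mm) .esScan(mm[ord], absd, u), 0)
  }
  sObs <- scoreAll(ci)
  sNull <- .withSeed(seed, vapply(seq_len(nPerm), function(b)
    scoreAll(sample.int(m, length(ci))), numeric(length(usable))))
  sNull <- matrix(sNull, nrow = length(usable))
  p <- vapply(seq_along(usable), function(i)
    .permP(sNull[i, ], sObs[i]), 0)
  res <- data.frame(pathway_id = usable, method = "GSEA", score = sObs,
                    p_value = p, fdr = bhFDR(p),
                    n_genes = vapply(memberOf, sum, 0L), row.names = NULL)
  res$significant <- res$fdr < fdrThreshold
  res[, c("pathway_id", "method", "score", "p_value", "fdr", "significant",
          "n_genes")]
}
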