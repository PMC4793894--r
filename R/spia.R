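# Signed perturbation propagation scoring (SPIA-style).

#' Gene perturbation factors by signed propagation
#'
#' Solves the perturbation recursion
#' \deqn{PF(i) = \Delta D(i) + \sum_{k \in parent(i)} \beta_{ki}
#'   \frac{PF(k)}{n_{child}(k)}}
#' exactly as a linear system, where `delta` holds the per-gene expression
#' change (0 for non-DE or unmeasured genes), `beta` the +1/-1 edge signs
#' and `n_child` the out-degrees. On certain cyclic graphs the system is
#' singular; then `PF = delta` is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param g a [PathwayGraph-class].
#' @param delta named numeric vector of expression changes covering every
#'   node of `g`.
#' @return named numeric vector of perturbation factors over the nodes,
#'   with attribute `degenerate` (logical).
#' @export
perturbationFactors <- function(g, delta) {
  nodes <- pathwayNodes(g)
  if (!all(nodes %in% names(delta)))
    stop("'delta' must cover every pathway node")
  d <- delta[nodes]
  p <- length(nodes)
  e <- pathwayEdges(g)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(e)) {
    nChild <- table(factor(e$from, levels = nodes))
    B[cbind(match(e$to, nodes), match(e$from, nodes))] <-
      e$sign / as.numeric(nChild[e$from])
  }
  M <- diag(p) - B
  if (rcond(M) < 1e-12) {
    pf <- d
    attr(pf, "degenerate") <- TRUE
    return(pf)
  }
  pf <- drop(solve(M, d))
  names(pf) <- nodes
  resid <- max(abs(M %*% pf - d))
  stopifnot(resid <= 1e-10 * (1 + sqrt(sum(d^2))))
  attr(pf, "degenerate") <- FALSE
  pf
}

#' Total accumulated pathway perturbation
#'
#' The net perturbation of a pathway is the sum over its genes of the
#' perturbation inherited from upstream, `PF(i) - delta(i)`.
#'
#' @param pf named numeric perturbation factors.
#' @param delta named numeric expression changes over the same genes.
#' @return numeric(1) total perturbation.
#' @export
totalPerturbation <- function(pf, delta) {
  if (!setequal(names(pf), names(delta)))
    stop("'pf' and 'delta' must cover the same genes")
  sum(pf - delta[names(pf)])
}

#' Over-representation tail probability for DE genes in a pathway
#'
#' Upper-tail hypergeometric probability that a pathway with
#' `pathwayMeasured` measured genes contains at least `kObserved` DE genes
#' when `deTotal` DE genes are spread at random over a background of
#' `background` measured genes.
#'
#' @param kObserved observed DE gene count in the pathway.
#' @param pathwayMeasured number of measured pathway genes.
#' @param deTotal total DE genes in the background.
#' @param background background (measured gene universe) size.
#' @return numeric(1) probability `P(X >= kObserved)`.
#' @export
pNDE <- function(kObserved, pathwayMeasured, deTotal, background) {
  if (background < pathwayMeasured || background < deTotal ||
      kObserved > min(pathwayMeasured, deTotal) || kObserved < 0)
    stop("impossible contingency counts")
  phyper(kObserved - 1, deTotal, background - deTotal, pathwayMeasured,
         lower.tail = FALSE)
}

#' Perturbation bootstrap probability
#'
#' Null model: the multiset of nonzero expression changes is reassigned to
#' a uniformly random subset of the pathway's nodes (all other nodes 0) and
#' the total perturbation recomputed. The p-value is two-sided around the
#' median of the null distribution:
#' `p = (1 + #\{|PB_null - med| >= |PB_obs - med|\}) / (nBoot + 1)`.
#'
#' @param g a [PathwayGraph-class].
#' @param deltaObserved named numeric vector of observed expression changes
#'   over the pathway nodes (zeros for non-DE genes).
#' @param nBoot number of bootstrap replicates (>= 100).
#' @param seed integer seed for the bootstrap (or NULL).
#' @return numeric(1) bootstrap p-value; 1 with a warning when all changes
#'   are zero.
#' @export
pPB <- function(g, deltaObserved, nBoot = 2000, seed = NULL) {
  if (nBoot < 100) stop("'nBoot' must be >= 100")
  nodes <- pathwayNodes(g)
  d <- deltaObserved[nodes]
  vals <- d[d != 0]
  if (!length(vals)) {
    warning("all expression changes are zero; perturbation p-value = 1")
    return(1)
  }
  p <- length(nodes)
  q <- length(vals)
  pf <- perturbationFactors(g, d)
  pbObs <- totalPerturbation(pf, d)
  # PB = colSums((M^-1 - I) D) for placements D; precompute the propagator.
  M <- .pfPropagator(g)
  pbNull <- .withSeed(seed, {
    D <- matrix(0, p, nBoot)
    pos <- replicate(nBoot, sample.int(p, q))
    D[cbind(as.vector(pos), rep(seq_len(nBoot), each = q))] <-
      rep(unname(vals), nBoot)
    if (is.null(M)) rep(0, nBoot) else colSums((M %*% D) - D)
  })
  med <- median(pbNull)
  (1 + sum(abs(pbNull - med) >= abs(pbObs - med))) / (nBoot + 1)
}

# Inverse propagation operator (I - B)^-1, or NULL when singular
# (the degenerate fallback PF = delta makes PB identically 0).
.pfPropagator <- function(g) {
  nodes <- pathwayNodes(g)
  p <- length(nodes)
  e <- pathwayEdges(g)
  B <- matrix(0, p, p)
  if (nrow(e)) {
    nChild <- table(factor(e$from, levels = nodes))
    B[cbind(match(e$to, nodes), match(e$from, nodes))] <-
      e$sign / as.numeric(nChild[e$from])
  }
  M <- diag(p) - B
  if (rcond(M) < 1e-12) return(NULL)
  solve(M)
}

#' Combine enrichment and perturbation probabilities
#'
#' Combines the two independent evidence channels into one global
#' probability: `c - c ln(c)` with `c = pNde * pPb` (the probability that
#' the product of two independent uniforms falls below `c`).
#'
#' @param pNde,pPb probabilities in (0, 1].
#' @return numeric(1) combined probability in (0, 1].
#' @export
spiaCombine <- function(pNde, pPb) {
  if (any(c(pNde, pPb) <= 0) || any(c(pNde, pPb) > 1))
    stop("both probabilities must lie in (0, 1]")
  cc <- pNde * pPb
  cc - cc * log(cc)
}

#' Run perturbation-propagation pathway scoring over a collection
#'
#' For each pathway, the expression changes of its DE genes (`delta` from
#' `de`, zero for every non-DE or unmeasured gene) are propagated through
#' the signed graph; the enrichment tail [pNDE()] and the perturbation
#' bootstrap [pPB()] are combined with [spiaCombine()], and pathway FDRs
#' are computed with [bhFDR()] over the combined scores.
#'
#' @param graphs list of [PathwayGraph-class] objects.
#' @param de DE table from [detectDE()].
#' @param background character vector of measured gene ids (defaults to the
#'   genes in `de`).
#' @param nBoot bootstrap replicates for [pPB()].
#' @param seed integer seed (or NULL).
#' @param fdrThreshold FDR cutoff for the significance flag.
#' @return data.frame with one row per analyzable pathway: `pathway_id`,
#'   `method`, `score` (combined probability), `p_value`, `fdr`,
#'   `significant`, `pNDE`, `pPB`, `totalPerturbation`, `degenerate`.
#'   Pathways without measured genes are skipped with a warning.
#' @export
runSpia <- function(graphs, de, background = de$gene, nBoot = 2000,
                    seed = NULL, fdrThreshold = 0.05) {
  if (!length(graphs)) stop("'graphs' must be nonempty")
  deGenes <- de$gene[de$de]
  deltaAll <- stats::setNames(ifelse(de$de, de$delta, 0), de$gene)
  rows <- lapply(seq_along(graphs), function(gi) {
    g <- graphs[[gi]]
    nodes <- pathwayNodes(g)
    measured <- intersect(nodes, background)
    if (!length(measured)) {
      warning(sprintf("pathway '%s' has no measured genes; skipped", g@id))
      return(NULL)
    }
    delta <- stats::setNames(rep(0, length(nodes)), nodes)
    hit <- intersect(nodes, names(deltaAll))
    delta[hit] <- deltaAll[hit]
    pf <- perturbationFactors(g, delta)
    pbTot <- totalPerturbation(pf, delta)
    pn <- pNDE(length(intersect(measured, deGenes)), length(measured),
               length(intersect(deGenes, background)), length(background))
    pb <- if (any(delta != 0))
      pPB(g, delta, nBoot = nBoot,
          seed = if (is.null(seed)) NULL else seed + gi)
    else 1
    data.frame(pathway_id = g@id, score = spiaCombine(pn, pb),
               pNDE = pn, pPB = pb, totalPerturbation = pbTot,
               degenerate = isTRUE(attr(pf, "degenerate")))
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway had measured genes")
  res$method <- "SPIA"
  res$p_value <- res$score
  res$fdr <- bhFDR(res$score)
  res$significant <- res$fdr < fdrThreshold
  res[, c("pathway_id", "method", "score", "p_value", "fdr", "significant",
          "pNDE", "pPB", "totalPerturbation", "degenerate")]
}
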