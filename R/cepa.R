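# Centrality-weighted overrepresentation scoring (CePa-ORA style).

#' Centrality-weighted overrepresentation score for one pathway
#'
#' For each of the six centrality criteria (see [centralities()]) the
#' pathway score is \eqn{S = \sum_{i \in G} centrality(i) \cdot de(i)},
#' i.e. the sum of centrality weights over the pathway's DE genes. The
#' null redraws `|deGenes|` genes uniformly without replacement from the
#' background and recomputes S; `p = (1 + #\{S_null >= S_obs\}) /
#' (nPerm + 1)`.
#'
#' @param g a [PathwayGraph-class].
#' @param deGenes character vector of DE gene ids (subset of `background`).
#' @param background character vector, the measured gene universe.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed (or NULL).
#' @return one-row data.frame with columns `pathway_id`, then
#'   `score.<criterion>` and `p.<criterion>` for the six criteria.
#' @export
cepaOra <- function(g, deGenes, background, nPerm = 999, seed = NULL) {
  if (nPerm < 100) stop("'nPerm' must be >= 100")
  if (!all(deGenes %in% background))
    stop("'deGenes' must be a subset of 'background'")
  cent <- centralities(g)
  C <- as.matrix(cent[, -1])  # nodes x 6 criteria
  rownames(C) <- cent$node
  nodeInBg <- cent$node %in% background
  obs <- colSums(C[cent$node %in% deGenes, , drop = FALSE])
  nDe <- length(unique(deGenes))
  if (nDe == 0L) {
    p <- rep(1, ncol(C))
  } else {
    SNull <- .withSeed(seed, {
      draw <- replicate(nPerm, {
        hit <- background[sample.int(length(background), nDe)]
        colSums(C[cent$node %in% hit, , drop = FALSE])
      })
      matrix(draw, nrow = ncol(C))
    })
    p <- vapply(seq_len(ncol(C)),
                function(j) .permP(SNull[j, ], obs[j]), 0)
  }
  out <- data.frame(pathway_id = g@id)
  for (j in seq_len(ncol(C))) {
    out[[paste0("score.", colnames(C)[j])]] <- obs[j]
    out[[paste0("p.", colnames(C)[j])]] <- p[j]
  }
  out
}

#' Run centrality-weighted overrepresentation over a pathway collection
#'
#' Applies [cepaOra()] to every pathway, converts each criterion's
#' p-values to FDR across pathways with [bhFDR()], and flags a pathway
#' significant when at least one of the six criteria has FDR below the
#' threshold.
#'
#' @param graphs list of [PathwayGraph-class] objects.
#' @param deGenes character vector of DE gene ids.
#' @param background measured gene universe.
#' @param nPerm permutations per pathway.
#' @param seed integer seed (or NULL).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return data.frame with one row per pathway: `pathway_id`, `method`,
#'   `score` (equal-weight S, i.e. the DE overlap count), `p_value` (the
#'   minimum over the six criteria), `fdr` (minimum per-criterion FDR),
#'   `significant` (any criterion FDR < threshold), `extras`
#'   (semicolon-separated `criterion=p` pairs) and the per-criterion
#'   `fdr.<criterion>` columns.
#' @export
runCepa <- function(graphs, deGenes, background, nPerm = 999, seed = NULL,
                    fdrThreshold = 0.05) {
  if (!length(graphs)) stop("'graphs' must be nonempty")
  deGenes <- intersect(deGenes, background)
  rows <- lapply(seq_along(graphs), function(gi)
    cepaOra(graphs[[gi]], deGenes, background, nPerm = nPerm,
            seed = if (is.null(seed)) NULL else seed + gi))
  res <- do.call(rbind, rows)
  pCols <- grep("^p\\.", colnames(res), value = TRUE)
  fdrMat <- vapply(pCols, function(cn) bhFDR(res[[cn]]),
                   numeric(nrow(res)))
  fdrMat <- matrix(fdrMat, nrow = nrow(res),
                   dimnames = list(NULL, sub("^p\\.", "fdr.", pCols)))
  out <- data.frame(pathway_id = res$pathway_id, method = "CePa",
                    score = res$score.equal.weight,
                    p_value = do.call(pmin, res[pCols]),
                    fdr = apply(fdrMat, 1, min),
                    significant = apply(fdrMat < fdrThreshold, 1, any))
  out$extras <- apply(res[pCols], 1, function(r)
    paste(sprintf("%s=%.6g", sub("^p\\.", "", pCols), r), collapse = ";"))
  cbind(out, as.data.frame(fdrMat))
}
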