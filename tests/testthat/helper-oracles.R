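# Independent brute-force oracles used to cross-check the implementation.

# Forward propagation of perturbation in topological order (DAGs only).
oraclePropagate <- function(g, delta) {
  nodes <- pathwayNodes(g)
  e <- pathwayEdges(g)
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                      vertices = data.frame(name = nodes))
  ord <- names(igraph::topo_sort(ig))
  nChild <- table(factor(e$from, levels = nodes))
  pf <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in ord) {
    inc <- e[e$to == i, , drop = FALSE]
    pf[i] <- delta[i] + sum(inc$sign * pf[inc$from] /
                              as.numeric(nChild[inc$from]))
  }
  pf[nodes]
}

# Signed path-sum matrix by exhaustive simple-path enumeration (DAGs).
oraclePathSum <- function(g) {
  nodes <- pathwayNodes(g)
  e <- pathwayEdges(g)
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                      vertices = data.frame(name = nodes))
  sgn <- stats::setNames(e$sign, paste(e$from, e$to))
  L <- diag(length(nodes))
  dimnames(L) <- list(nodes, nodes)
  for (k in nodes) for (i in setdiff(nodes, k)) {
    paths <- igraph::all_simple_paths(ig, from = k, to = i, mode = "out")
    L[i, k] <- sum(vapply(paths, function(p) {
      nm <- names(p)
      prod(sgn[paste(nm[-length(nm)], nm[-1])])
    }, 0))
  }
  L
}

# Upper-tail hypergeometric by direct mass summation.
oracleHyperTail <- function(k, K, nDe, N) {
  kk <- k:min(K, nDe)
  sum(choose(nDe, kk) * choose(N - nDe, K - kk)) / choose(N, K)
}

# BH step-up by its min-over-tail definition.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m))
    padj[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
  padj
}

# Enrichment score by evaluating the two cumulative sums at every rank.
oracleES <- function(member, absd, u) {
  n <- length(member); p <- sum(member)
  w <- ifelse(member, absd^u, 0)
  if (sum(w) == 0) w[member] <- 1
  best <- 0
  for (r in seq_len(n)) {
    ph <- sum(w[seq_len(r)]) / sum(w)
    pm <- sum(!member[seq_len(r)]) / (n - p)
    best <- max(best, abs(ph - pm))
  }
  best
}
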