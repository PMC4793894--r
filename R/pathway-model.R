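# Graph-derived quantities shared by the topology-based scorers.

.toIgraph <- function(g) {
  igraph::graph_from_data_frame(
    pathwayEdges(g)[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = pathwayNodes(g)))
}

#' Node centralities used by centrality-weighted overrepresentation
#'
#' Computes the six centrality criteria used to weight differentially
#' expressed genes: equal weight (1 for every node), in-degree, out-degree,
#' directed unnormalized betweenness, in-reach (length in edges of the
#' longest shortest path from any node able to reach the node, i.e. toward
#' the root side) and out-reach (longest shortest path to any node
#' reachable from the node, i.e. toward the leaf side). Reach criteria
#' count edges; nodes with no reachable targets get reach 0.
#'
#' @param g a [PathwayGraph-class].
#' @return data.frame with one row per node and columns `node`,
#'   `equal.weight`, `in.degree`, `out.degree`, `betweenness`, `in.reach`,
#'   `out.reach`.
#' @rdname centralities
#' @export
setMethod("centralities", "PathwayGraph", function(g) {
  if (length(pathwayNodes(g)) == 0L) stop("pathway graph has no nodes")
  ig <- .toIgraph(g)
  dOut <- igraph::distances(ig, mode = "out")
  dIn <- igraph::distances(ig, mode = "in")
  maxFinite <- function(x) {
    x <- x[is.finite(x)]
    if (length(x)) max(x) else 0
  }
  data.frame(
    node = pathwayNodes(g),
    equal.weight = 1,
    in.degree = as.numeric(igraph::degree(ig, mode = "in")),
    out.degree = as.numeric(igraph::degree(ig, mode = "out")),
    betweenness = as.numeric(igraph::betweenness(ig, directed = TRUE)),
    in.reach = apply(dIn, 1, maxFinite),
    out.reach = apply(dOut, 1, maxFinite),
    row.names = NULL
  )
})

.signedAdjacency <- function(g) {
  p <- length(pathwayNodes(g))
  A <- matrix(0, p, p, dimnames = list(pathwayNodes(g), pathwayNodes(g)))
  e <- pathwayEdges(g)
  if (nrow(e)) A[cbind(match(e$to, pathwayNodes(g)),
                       match(e$from, pathwayNodes(g)))] <- e$sign
  A
}

.isAcyclic <- function(g) {
  igraph::is_dag(.toIgraph(g))
}

#' Signed influence matrix of a pathway graph
#'
#' Builds the damped signed path-sum influence matrix
#' \eqn{\Lambda = (I - \rho A)^{-1}}, where `A[i, k]` is the edge sign of
#' `k -> i` and \eqn{\rho} is the damping scaled by the spectral radius of
#' `A` so that \eqn{\rho A} is a contraction. On a directed acyclic graph
#' with damping 1, \eqn{\Lambda[i, k]} equals the sum over all directed
#' paths from `k` to `i` of the product of edge signs.
#'
#' @param g a [PathwayGraph-class].
#' @param damping damping factor in (0, 1]; defaults to 1 on acyclic graphs
#'   and 0.9 on cyclic graphs.
#' @return numeric matrix over the pathway nodes (rows = influenced node,
#'   columns = influencing node).
#' @rdname influenceMatrix
#' @export
setMethod("influenceMatrix", "PathwayGraph", function(g, damping = NULL) {
  p <- length(pathwayNodes(g))
  if (p == 0L) stop("pathway graph has no nodes")
  A <- .signedAdjacency(g)
  if (is.null(damping)) damping <- if (.isAcyclic(g)) 1 else 0.9
  if (damping <= 0 || damping > 1) stop("'damping' must be in (0, 1]")
  sr <- if (p == 1L) abs(A[1, 1]) else
    max(Mod(eigen(A, only.values = TRUE)$values))
  rho <- if (sr > 1e-12) damping / sr else damping
  M <- diag(p) - rho * A
  if (rcond(M) < 1e-12)
    stop("influence system is singular; use a smaller damping")
  L <- solve(M)
  dimnames(L) <- dimnames(A)
  L
})
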