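#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median p.adjust phyper pt quantile rnorm runif sd var
#'   lowess setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# ExpressionDataset
# ---------------------------------------------------------------------------

#' Expression dataset with case/control sample groups
#'
#' An `ExpressionDataset` is a [SummarizedExperiment::SummarizedExperiment]
#' holding one assay `"exprs"` (genes x samples), a per-sample `group`
#' column in `colData` with levels `"case"` and `"control"`, and a `scaled`
#' flag recording whether values are on the log2(x + 1) scale (`TRUE`) or
#' raw non-negative intensities (`FALSE`).
#'
#' @slot scaled logical(1); `TRUE` once [logScale()] has been applied.
#' @seealso [ExpressionDataset()], [logScale()], [detectDE()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset",
  contains = "SummarizedExperiment",
  slots = c(scaled = "logical")
)

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  if (length(object@scaled) != 1L || is.na(object@scaled))
    msg <- c(msg, "'scaled' must be TRUE or FALSE")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else if (!all(cd$group %in% c("case", "control"))) {
    msg <- c(msg, "sample groups must be 'case' or 'control'")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg) == 0L && "exprs" %in% SummarizedExperiment::assayNames(object)) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(v)) msg <- c(msg, "expression values must not contain NA")
    else if (!isTRUE(object@scaled) && length(v) && min(v) < 0)
      msg <- c(msg, "unscaled expression values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionDataset
#'
#' @param values numeric matrix, genes x samples, with row and column names.
#' @param groups character vector of `"case"`/`"control"`, one per sample,
#'   or a named vector matched against `colnames(values)`.
#' @param scaled logical(1); whether `values` are already log2(x + 1) scaled.
#' @return An [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(rpois(20, 50), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ds <- ExpressionDataset(m, c("case", "case", "case", "control", "control"))
#' sampleGroups(ds)
#' @export
ExpressionDataset <- function(values, groups, scaled = FALSE) {
  values <- as.matrix(values)
  if (!is.null(names(groups))) groups <- unname(groups[colnames(values)])
  if (length(groups) != ncol(values))
    stop("'groups' must supply one label per sample column")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(values))
  )
  new("ExpressionDataset", se, scaled = isTRUE(scaled))
}

# ---------------------------------------------------------------------------
# PathwayGraph
# ---------------------------------------------------------------------------

#' Signed directed pathway graph
#'
#' Nodes are gene identifiers; each edge carries a sign: +1 for activation,
#' -1 for inhibition. Parent sets and child counts used by perturbation
#' propagation are derived from the edge list.
#'
#' @slot id character(1) pathway identifier.
#' @slot name character(1) display name.
#' @slot nodes character vector of gene identifiers (order preserved).
#' @slot edges data.frame with columns `from`, `to` (gene ids) and
#'   `sign` (+1/-1).
#' @seealso [PathwayGraph()], [centralities()], [influenceMatrix()],
#'   [perturbationFactors()]
#' @exportClass PathwayGraph
setClass("PathwayGraph",
  slots = c(id = "character", name = "character",
            nodes = "character", edges = "data.frame")
)

setValidity("PathwayGraph", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be a single string")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node ids")
  e <- object@edges
  if (!all(c("from", "to", "sign") %in% colnames(e))) {
    msg <- c(msg, "edges need columns 'from', 'to', 'sign'")
  } else if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a declared node")
    if (!all(e$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
      msg <- c(msg, "duplicate (source, target) edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PathwayGraph
#'
#' @param id pathway identifier.
#' @param nodes character vector of gene ids; endpoints of `edges` missing
#'   from `nodes` are appended.
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1);
#'   defaults to no edges.
#' @param name display name; defaults to `id`.
#' @return A [PathwayGraph-class] object.
#' @examples
#' pg <- PathwayGraph("P1", c("a", "b", "c"),
#'                    data.frame(from = c("a", "b"), to = c("b", "c"),
#'                               sign = c(1, -1)))
#' centralities(pg)
#' @export
PathwayGraph <- function(id, nodes = character(),
                         edges = data.frame(from = character(),
                                            to = character(),
                                            sign = numeric()),
                         name = id) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.numeric(edges$sign)
  nodes <- unique(c(as.character(nodes), edges$from, edges$to))
  new("PathwayGraph", id = id, name = name, nodes = nodes,
      edges = edges[, c("from", "to", "sign")])
}

# ---------------------------------------------------------------------------
# GeneSetCollection
# ---------------------------------------------------------------------------

#' Collection of unstructured gene sets
#'
#' The flat (list-based) view of pathways used by the EASE, GSEA and
#' Pathifier scorers: a named list mapping set ids to character vectors of
#' gene identifiers, plus display names.
#'
#' @slot sets named list of character vectors; no set empty, genes unique
#'   within a set.
#' @slot setNames character vector of display names, parallel to `sets`.
#' @seealso [GeneSetCollection()], [readGMT()], [asGeneSetCollection()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
  slots = c(sets = "list", setNames = "character")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      msg <- c(msg, "sets must have unique names")
    if (any(lengths(s) == 0L)) msg <- c(msg, "empty gene sets are not allowed")
    if (any(vapply(s, anyDuplicated, 0L) > 0L))
      msg <- c(msg, "gene ids must be unique within a set")
  }
  if (length(object@setNames) != length(s))
    msg <- c(msg, "'setNames' must parallel 'sets'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param setNames display names (defaults to the list names).
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, setNames = names(sets)) {
  new("GeneSetCollection", sets = lapply(sets, as.character),
      setNames = as.character(setNames))
}

# ---------------------------------------------------------------------------
# PrincipalCurve
# ---------------------------------------------------------------------------

#' Fitted principal curve
#'
#' A one-dimensional curve through a point cloud, stored as an ordered
#' polyline with cumulative arc-length parameters, as produced by
#' [fitPrincipalCurve()].
#'
#' @slot polyline numeric matrix of curve points (rows ordered along the
#'   curve).
#' @slot arcLength numeric vector of cumulative arc length at each polyline
#'   point (strictly increasing, starts at 0).
#' @slot iterations integer(1) number of projection/smoothing iterations run.
#' @slot msd numeric(1) final mean squared projection distance.
#' @slot converged logical(1).
#' @exportClass PrincipalCurve
setClass("PrincipalCurve",
  slots = c(polyline = "matrix", arcLength = "numeric",
            iterations = "integer", msd = "numeric", converged = "logical")
)

setValidity("PrincipalCurve", function(object) {
  msg <- character()
  if (nrow(object@polyline) < 2L) msg <- c(msg, "polyline needs >= 2 points")
  if (length(object@arcLength) != nrow(object@polyline))
    msg <- c(msg, "one arc-length value per polyline point is required")
  if (any(diff(object@arcLength) <= 0))
    msg <- c(msg, "arc-length parameters must be strictly increasing")
  if (length(msg)) msg else TRUE
})
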