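#' @rdname ExpressionDataset-class
#' @param x,object an object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname logScale
#' @export
setGeneric("logScale", function(x) standardGeneric("logScale"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("pathwayNodes", function(x) standardGeneric("pathwayNodes"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("pathwayEdges", function(x) standardGeneric("pathwayEdges"))

#' @rdname centralities
#' @export
setGeneric("centralities", function(g) standardGeneric("centralities"))

#' @rdname influenceMatrix
#' @export
setGeneric("influenceMatrix",
           function(g, damping = NULL) standardGeneric("influenceMatrix"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

# -- accessor methods -------------------------------------------------------

#' @rdname ExpressionDataset-class
#' @export
setMethod("exprValues", "ExpressionDataset", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname ExpressionDataset-class
#' @export
setMethod("sampleGroups", "ExpressionDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$group))

#' @rdname ExpressionDataset-class
#' @export
setMethod("isScaled", "ExpressionDataset", function(x) x@scaled)

#' @rdname PathwayGraph-class
#' @export
setMethod("pathwayNodes", "PathwayGraph", function(x) x@nodes)

#' @rdname PathwayGraph-class
#' @export
setMethod("pathwayEdges", "PathwayGraph", function(x) x@edges)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @param i set index or name.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

# -- show methods -----------------------------------------------------------

setMethod("show", "ExpressionDataset", function(object) {
  gr <- table(sampleGroups(object))
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (isScaled(object)) "log2(x+1) scaled" else "unscaled"))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s=%d", names(gr), gr), collapse = ", ")))
})

setMethod("show", "PathwayGraph", function(object) {
  cat(sprintf("PathwayGraph '%s': %d nodes, %d edges (%d inhibitory)\n",
              object@id, length(object@nodes), nrow(object@edges),
              sum(object@edges$sign < 0)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets, sizes %s\n",
              length(object@sets),
              if (length(object@sets))
                paste(range(lengths(object@sets)), collapse = "-")
              else "-"))
})

setMethod("show", "PrincipalCurve", function(object) {
  cat(sprintf(
    "PrincipalCurve: %d points in %dd, length %.3f, msd %.4g (%d iter%s)\n",
    nrow(object@polyline), ncol(object@polyline),
    max(object@arcLength), object@msd, object@iterations,
    if (object@converged) ", converged" else ""))
})
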