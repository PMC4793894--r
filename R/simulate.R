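# Synthetic data generators: expression matrices, signed pathway graphs,
# control-only artificial null data sets, and pathway signal injection.

#' Simulation configuration for synthetic expression data
#'
#' The two regimes mirror the two study settings the benchmark is built
#' around: `"large"` (cancer-like, many strongly shifted genes: 1500 DE
#' genes at a log2 shift of 1.5) and `"small"` (diabetes-like, under 20
#' weakly shifted genes: 15 DE genes at 0.6). Baseline log2 abundances are
#' normal with location 6 and scale 1 (typical microarray intensity
#' range); residual noise is Gaussian with sd 0.5 on the log2 scale.
#'
#' @param regime `"large"`, `"small"`, or `"custom"`.
#' @param nGenes,nCase,nControl dimensions (counts; samples >= 2 each).
#' @param nDe number of truly shifted genes (0 allowed for pure nulls).
#' @param effectSize log2 shift added to case samples of DE genes (>= 0).
#' @param baselineLocation,baselineScale log2-scale normal parameters of
#'   the per-gene baseline.
#' @param noiseSd residual sd on the log2 scale.
#' @param seed integer seed (or NULL).
#' @return list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(regime = c("custom", "large", "small"),
                             nGenes = 2000, nCase = 10, nControl = 10,
                             nDe = NULL, effectSize = NULL,
                             baselineLocation = 6, baselineScale = 1,
                             noiseSd = 0.5, seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(nDe))
    nDe <- switch(regime, large = 1500, small = 15, custom = 0)
  if (is.null(effectSize))
    effectSize <- switch(regime, large = 1.5, small = 0.6, custom = 0)
  cfg <- list(regime = regime, nGenes = nGenes, nCase = nCase,
              nControl = nControl, nDe = nDe, effectSize = effectSize,
              baselineLocation = baselineLocation,
              baselineScale = baselineScale, noiseSd = noiseSd, seed = seed)
  if (cfg$nDe > cfg$nGenes) stop("'nDe' must not exceed 'nGenes'")
  if (cfg$effectSize < 0) stop("'effectSize' must be >= 0")
  if (cfg$nCase < 2 || cfg$nControl < 2) stop("need >= 2 samples per group")
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate an unscaled expression dataset with known DE genes
#'
#' Values are generated on the log2 scale as per-gene baseline + group
#' shift + Gaussian noise, then transformed back to the intensity scale as
#' `2^x - 1` (clipped at 0), so that [logScale()] recovers the log2-scale
#' representation. Exactly `nDe` genes carry the case-group shift; their
#' ids are returned as the truth. Bit-reproducible for a fixed seed.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `dataset` (unscaled [ExpressionDataset-class]) and
#'   `truth` (character vector of shifted gene ids).
#' @export
simulateExpression <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  .withSeed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$nGenes))
    samples <- c(sprintf("case_%02d", seq_len(cfg$nCase)),
                 sprintf("ctrl_%02d", seq_len(cfg$nControl)))
    groups <- rep(c("case", "control"), c(cfg$nCase, cfg$nControl))
    baseline <- rnorm(cfg$nGenes, cfg$baselineLocation, cfg$baselineScale)
    truth <- if (cfg$nDe > 0) sort(sample(genes, cfg$nDe)) else character()
    shift <- outer(genes %in% truth * cfg$effectSize, groups == "case")
    logVals <- baseline + shift +
      matrix(rnorm(cfg$nGenes * length(samples), 0, cfg$noiseSd),
             cfg$nGenes)
    values <- pmax(2^logVals - 1, 0)
    dimnames(values) <- list(genes, samples)
    list(dataset = ExpressionDataset(values, groups, scaled = FALSE),
         truth = truth)
  })
}

#' Configuration for random pathway graph simulation
#'
#' @param nPathways number of graphs.
#' @param sizeRange integer(2), min/max node counts (min >= 3).
#' @param edgeDensity probability of each admissible ordered pair being an
#'   edge, in (0, 1).
#' @param inhibitionFraction fraction of edges with sign -1, in \[0, 1\].
#' @param acyclic generate DAGs by topological-order edge sampling
#'   (default TRUE); otherwise edges are sampled over all ordered pairs.
#' @param seed integer seed (or NULL).
#' @return list of class `"graphSimulationConfig"`.
#' @export
graphSimulationConfig <- function(nPathways = 20, sizeRange = c(10, 30),
                                  edgeDensity = 0.15,
                                  inhibitionFraction = 0.25,
                                  acyclic = TRUE, seed = NULL) {
  if (sizeRange[1] < 3) stop("minimum pathway size is 3")
  if (edgeDensity <= 0 || edgeDensity >= 1)
    stop("'edgeDensity' must be in (0, 1)")
  if (inhibitionFraction < 0 || inhibitionFraction > 1)
    stop("'inhibitionFraction' must be in [0, 1]")
  structure(list(nPathways = nPathways, sizeRange = sizeRange,
                 edgeDensity = edgeDensity,
                 inhibitionFraction = inhibitionFraction,
                 acyclic = acyclic, seed = seed),
            class = "graphSimulationConfig")
}

#' Simulate random signed pathway graphs
#'
#' DAGs are built by sampling edges only from lower to higher position in
#' a random node order (so acyclicity holds by construction); cyclic
#' graphs sample over all ordered pairs. Node (gene) ids are drawn
#' without replacement per pathway from `geneUniverse`, so overlap between
#' pathways and simulated DE genes is controllable.
#'
#' @param cfg a [graphSimulationConfig()].
#' @param geneUniverse character vector of available gene ids.
#' @return list with `graphs` (list of [PathwayGraph-class]) and `sets`
#'   (the flattened [GeneSetCollection-class] view).
#' @export
simulatePathways <- function(cfg, geneUniverse) {
  stopifnot(inherits(cfg, "graphSimulationConfig"))
  graphs <- .withSeed(cfg$seed, lapply(seq_len(cfg$nPathways), function(k) {
    size <- cfg$sizeRange[1] +
      sample.int(cfg$sizeRange[2] - cfg$sizeRange[1] + 1L, 1L) - 1L
    genes <- sample(geneUniverse, size)
    pairs <- expand.grid(from = seq_len(size), to = seq_len(size))
    pairs <- if (cfg$acyclic) pairs[pairs$from < pairs$to, ]
             else pairs[pairs$from != pairs$to, ]
    keep <- runif(nrow(pairs)) < cfg$edgeDensity
    e <- pairs[keep, , drop = FALSE]
    sign <- ifelse(runif(nrow(e)) < cfg$inhibitionFraction, -1, 1)
    PathwayGraph(sprintf("path%03d", k), nodes = genes,
                 edges = data.frame(from = genes[e$from],
                                    to = genes[e$to], sign = sign))
  }))
  list(graphs = graphs, sets = asGeneSetCollection(graphs))
}

#' Build artificial null data sets from control samples
#'
#' Keeps only the control columns of `ds` and relabels them by an
#' independent uniform split into `floor(m/2)` artificial cases and the
#' remaining artificial controls, repeated `nSets` times. By construction
#' the resulting data sets carry no group signal while preserving the real
#' between-sample heterogeneity; any significant pathway found in them is
#' a false positive.
#'
#' @param ds an [ExpressionDataset-class] with at least 6 control samples.
#' @param nSets number of null data sets (default 5).
#' @param seed integer seed (or NULL).
#' @return list of [ExpressionDataset-class] objects (scaled flag
#'   inherited from `ds`).
#' @export
makeArtificialNulls <- function(ds, nSets = 5, seed = NULL) {
  ri <- .controlIdx(ds)
  if (length(ri) < 6L) stop("need at least 6 control samples")
  v <- exprValues(ds)[, ri, drop = FALSE]
  m <- length(ri)
  .withSeed(seed, lapply(seq_len(nSets), function(k) {
    fakeCase <- sample.int(m, floor(m / 2))
    groups <- rep("control", m)
    groups[fakeCase] <- "case"
    ExpressionDataset(v, groups, scaled = isScaled(ds))
  }))
}

#' Inject a case-group expression shift into one pathway
#'
#' Adds `effectSize` (log2 scale) to the case samples of a random
#' `fraction` of the pathway's measured genes. On unscaled data the shift
#' is applied in log2 space and transformed back, so it corresponds to the
#' same fold change either way.
#'
#' @param ds an [ExpressionDataset-class].
#' @param graph a [PathwayGraph-class].
#' @param effectSize log2 shift (>= 0; 0 leaves the data unchanged).
#' @param fraction fraction of measured pathway genes to shift, in (0, 1].
#' @param seed integer seed (or NULL).
#' @return An [ExpressionDataset-class] with attribute `injectedGenes`.
#' @export
injectPathwaySignal <- function(ds, graph, effectSize, fraction = 1,
                                seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  if (effectSize < 0) stop("'effectSize' must be >= 0")
  genes <- intersect(pathwayNodes(graph), rownames(ds))
  if (!length(genes)) stop("no pathway gene is measured")
  k <- ceiling(fraction * length(genes))
  target <- .withSeed(seed, sample(genes, k))
  v <- exprValues(ds)
  ci <- .caseIdx(ds)
  if (effectSize > 0 && length(ci)) {
    block <- v[target, ci, drop = FALSE]
    v[target, ci] <- if (isScaled(ds)) block + effectSize
                     else 2^(log2(block + 1) + effectSize) - 1
  }
  out <- ExpressionDataset(v, sampleGroups(ds), scaled = isScaled(ds))
  attr(out, "injectedGenes") <- sort(target)
  out
}
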