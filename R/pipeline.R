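# End-to-end pipeline: run all scorers on a dataset collection, apply the
# fixed significance rules, and summarise cross-dataset consistency.

.allMethods <- c("SPIA", "CePa", "NetGSA", "DAVID", "GSEA", "Pathifier")

#' Run the selected pathway scorers on one dataset
#'
#' Enforces the per-method scaling conventions: GSEA always consumes
#' unscaled data, the network-based statistic and deregulation scoring
#' always consume log2(x + 1) scaled data, and the DE-list methods (SPIA,
#' CePa, DAVID) consume the form selected by `listInput` (both forms are
#' legitimate; scaling changes their DE gene lists). Significance is
#' always FDR < `deThreshold` per method, with the any-of-six-centralities
#' rule for CePa.
#'
#' @param ds an unscaled [ExpressionDataset-class]; the scaled form is
#'   derived internally.
#' @param graphs list of [PathwayGraph-class] objects (their flattened
#'   node sets serve as the gene sets for the list-based scorers).
#' @param methods subset of `c("SPIA", "CePa", "NetGSA", "DAVID", "GSEA",
#'   "Pathifier")`.
#' @param listInput `"scaled"` or `"unscaled"`: the input form for the
#'   DE-list methods.
#' @param deThreshold FDR cutoff used both for DE calls and pathway
#'   significance (default 0.05).
#' @param nPerm permutations for the permutation-based scorers.
#' @param nBoot bootstrap replicates for the perturbation scorer.
#' @param gseaU weight exponent for [runGsea()].
#' @param seed integer seed (or NULL); sub-seeds are derived per method.
#' @return data.frame with columns `pathway_id`, `method`, `score`,
#'   `p_value`, `fdr`, `significant`, `extras`, sorted by
#'   `(method, fdr, pathway_id)`.
#' @export
runAllMethods <- function(ds, graphs, methods = .allMethods,
                          listInput = c("scaled", "unscaled"),
                          deThreshold = 0.05, nPerm = 999, nBoot = 2000,
                          gseaU = 1, seed = NULL) {
  methods <- match.arg(methods, .allMethods, several.ok = TRUE)
  listInput <- match.arg(listInput)
  if (isScaled(ds))
    stop("provide unscaled data; scaling is handled per method")
  dsScaled <- logScale(ds)
  sets <- asGeneSetCollection(graphs)
  background <- rownames(ds)
  sub <- function(k) if (is.null(seed)) NULL else seed + 1000L * k
  de <- NULL
  if (any(c("SPIA", "CePa", "DAVID") %in% methods)) {
    de <- detectDE(if (listInput == "scaled") dsScaled else ds,
                   threshold = deThreshold)
  }
  pieces <- list()
  if ("SPIA" %in% methods)
    pieces$SPIA <- runSpia(graphs, de, background, nBoot = nBoot,
                           seed = sub(1), fdrThreshold = deThreshold)
  if ("CePa" %in% methods)
    pieces$CePa <- runCepa(graphs, de$gene[de$de], background,
                           nPerm = nPerm, seed = sub(2),
                           fdrThreshold = deThreshold)
  if ("NetGSA" %in% methods)
    pieces$NetGSA <- runNetgsa(dsScaled, graphs, nPerm = nPerm,
                               seed = sub(3), fdrThreshold = deThreshold)
  if ("DAVID" %in% methods)
    pieces$DAVID <- runEase(sets, de$gene[de$de], background,
                            fdrThreshold = deThreshold)
  if ("GSEA" %in% methods)
    pieces$GSEA <- runGsea(ds, sets, u = gseaU, nPerm = nPerm,
                           seed = sub(4), fdrThreshold = deThreshold)
  if ("Pathifier" %in% methods) {
    scoreTables <- lapply(graphs, function(g)
      pathifierScores(dsScaled, pathwayNodes(g)))
    names(scoreTables) <- vapply(graphs, function(g) g@id, "")
    pieces$Pathifier <- pathifierGroupTest(scoreTables,
                                           fdrThreshold = deThreshold)
  }
  core <- c("pathway_id", "method", "score", "p_value", "fdr",
            "significant")
  res <- do.call(rbind, lapply(pieces, function(p) {
    p$extras <- if ("extras" %in% colnames(p)) p$extras else ""
    p[, c(core, "extras")]
  }))
  rownames(res) <- NULL
  res[order(res$method, res$fdr, res$pathway_id), ]
}

#' Run the full comparison pipeline over real and artificial datasets
#'
#' Applies [runAllMethods()] to every real and artificial dataset, writes
#' (optionally) one sorted results TSV per dataset plus a run manifest,
#' and summarises each method's cross-dataset behaviour with
#' [consistencyScore()] when at least two real datasets are given.
#'
#' @param datasets named list of unscaled [ExpressionDataset-class]
#'   objects (the real comparisons).
#' @param graphs list of [PathwayGraph-class] objects.
#' @param artificialDatasets named list of unscaled null datasets
#'   (default none).
#' @param methods,listInput,deThreshold,nPerm,nBoot,gseaU,seed passed to
#'   [runAllMethods()]; per-dataset sub-seeds are derived from `seed`.
#' @param outDir optional directory for `results_<dataset>.tsv`,
#'   `consistency.tsv` and `manifest.txt`.
#' @return list with `results` (named list of per-dataset tables),
#'   `artificialResults`, `consistency` (data.frame or NULL) and
#'   `manifest` (character vector).
#' @export
runPipeline <- function(datasets, graphs, artificialDatasets = list(),
                        methods = .allMethods,
                        listInput = c("scaled", "unscaled"),
                        deThreshold = 0.05, nPerm = 999, nBoot = 2000,
                        gseaU = 1, seed = NULL, outDir = NULL) {
  listInput <- match.arg(listInput)
  if (is.null(names(datasets)) && length(datasets))
    names(datasets) <- sprintf("dataset%02d", seq_along(datasets))
  if (is.null(names(artificialDatasets)) && length(artificialDatasets))
    names(artificialDatasets) <-
      sprintf("artificial%02d", seq_along(artificialDatasets))
  runOne <- function(ds, k)
    runAllMethods(ds, graphs, methods = methods, listInput = listInput,
                  deThreshold = deThreshold, nPerm = nPerm, nBoot = nBoot,
                  gseaU = gseaU,
                  seed = if (is.null(seed)) NULL else seed + 100000L * k)
  results <- mapply(runOne, datasets, seq_along(datasets),
                    SIMPLIFY = FALSE)
  artResults <- mapply(runOne, artificialDatasets,
                       length(datasets) + seq_along(artificialDatasets),
                       SIMPLIFY = FALSE)
  consistency <- NULL
  if (length(results) >= 2) {
    consistency <- do.call(rbind, lapply(intersect(.allMethods, methods),
      function(meth) {
        sig <- lapply(results, function(r)
          r$pathway_id[r$method == meth & r$significant])
        art <- lapply(artResults, function(r)
          r$pathway_id[r$method == meth & r$significant])
        consistencyScore(sig, art, nPathways = length(graphs),
                         method = meth)
      }))
  }
  manifest <- c(
    sprintf("pathwaybench %s, R %s.%s", packageVersion("pathwaybench"),
            R.version$major, R.version$minor),
    sprintf("seed: %s", if (is.null(seed)) "NULL" else seed),
    sprintf("methods: %s", paste(methods, collapse = ",")),
    sprintf("listInput: %s; deThreshold: %g; nPerm: %d; nBoot: %d; u: %g",
            listInput, deThreshold, nPerm, nBoot, gseaU),
    sprintf("datasets: %s", paste(names(datasets), collapse = ",")),
    sprintf("artificial: %s",
            paste(names(artificialDatasets), collapse = ",")))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(results))
      writeResultsTsv(results[[nm]],
                      file.path(outDir, sprintf("results_%s.tsv", nm)))
    for (nm in names(artResults))
      writeResultsTsv(artResults[[nm]],
                      file.path(outDir, sprintf("results_%s.tsv", nm)))
    if (!is.null(consistency))
      write.table(consistency, file.path(outDir, "consistency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(manifest, file.path(outDir, "manifest.txt"))
  }
  list(results = results, artificialResults = artResults,
       consistency = consistency, manifest = manifest)
}

#' Consistency scores computable from artificial null data alone
#'
#' The negative-control benchmark: generate ten artificial null datasets
#' by independently splitting a pool of homogeneous control samples into
#' fake case/control groups (five splits analysed as unscaled input for
#' the DE-list methods, five as log2(x + 1) scaled input; methods with a
#' fixed input convention always receive their required form), run every
#' scorer with FDR < 0.05 calls, then randomly divide the ten outcome
#' sets into a "real" half and an "artificial" half and evaluate the
#' consistency score per method. Because the data carry no signal, every
#' method's score should be essentially zero.
#'
#' @param seed integer seed driving every random choice.
#' @param nGenes,nControls,nPathways scale of the synthetic study
#'   (defaults 500 genes, 20 controls, 20 pathways).
#' @param nSplits control splits per scaling form (default 5).
#' @param nPerm,nBoot permutation/bootstrap sizes for the scorers
#'   (defaults 199/499, the benchmark's reduced sizes).
#' @param deThreshold FDR cutoff (default 0.05).
#' @return data.frame with one row per method: `method`, `score`, `alpha`
#'   and the beta columns; attribute `maxScore` holds the maximum.
#' @export
runArtificialNullBenchmark <- function(seed, nGenes = 500, nControls = 20,
                                       nPathways = 20, nSplits = 5,
                                       nPerm = 199, nBoot = 499,
                                       deThreshold = 0.05) {
  cfg <- simulationConfig("custom", nGenes = nGenes, nCase = 2,
                          nControl = nControls, nDe = 0, effectSize = 0,
                          seed = seed)
  pool <- simulateExpression(cfg)$dataset
  graphs <- simulatePathways(
    graphSimulationConfig(nPathways = nPathways, seed = seed + 7L),
    geneUniverse = rownames(pool))$graphs
  splits <- lapply(seq_len(2L * nSplits), function(s)
    makeArtificialNulls(pool, nSets = 1, seed = seed * 101L + s)[[1]])
  forms <- rep(c("unscaled", "scaled"), each = nSplits)
  outcome <- lapply(seq_along(splits), function(k)
    runAllMethods(splits[[k]], graphs,
                  listInput = forms[k], deThreshold = deThreshold,
                  nPerm = nPerm, nBoot = nBoot,
                  seed = seed + 100000L * k))
  realIdx <- .withSeed(seed * 977L,
                       sample.int(length(outcome), length(outcome) %/% 2))
  report <- do.call(rbind, lapply(.allMethods, function(meth) {
    sig <- lapply(outcome, function(r)
      r$pathway_id[r$method == meth & r$significant])
    consistencyScore(sig[realIdx], sig[-realIdx],
                     nPathways = length(graphs), method = meth)
  }))
  attr(report, "maxScore") <- max(report$score)
  report
}
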