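test_that("expression simulation is reproducible and recovers its truth", {
  cfg <- simulationConfig("custom", nGenes = 300, nDe = 30,
                          effectSize = 2, seed = 71)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(exprValues(a$dataset), exprValues(b$dataset))
  expect_identical(a$truth, b$truth)
  expect_length(a$truth, 30)
  expect_false(isScaled(a$dataset))
  expect_gte(min(exprValues(a$dataset)), 0)

  # the strong-signal configuration is recoverable by the DE detector
  big <- simulateExpression(simulationConfig("custom", nGenes = 2000,
                                             nDe = 400, effectSize = 2,
                                             seed = 72))
  de <- detectDE(logScale(big$dataset))
  expect_gte(mean(big$truth %in% de$gene[de$de]), 0.8)

  # a zero-effect configuration is distributionally null
  nul <- simulateExpression(simulationConfig("custom", nGenes = 1000,
                                             nDe = 50, effectSize = 0,
                                             seed = 73))
  deN <- detectDE(logScale(nul$dataset))
  expect_lte(mean(deN$de), 0.05)
})

test_that("regime presets encode the two study settings", {
  large <- simulationConfig("large")
  small <- simulationConfig("small")
  expect_equal(c(large$nDe, large$effectSize), c(1500, 1.5))
  expect_equal(c(small$nDe, small$effectSize), c(15, 0.6))
  expect_error(simulationConfig("custom", nGenes = 10, nDe = 20), "exceed")
  expect_error(simulationConfig("custom", nCase = 1), "2 samples")
})

test_that("simulated pathway graphs respect their configuration", {
  universe <- sprintf("g%04d", 1:500)
  sim <- simulatePathways(graphSimulationConfig(nPathways = 10, seed = 74),
                          universe)
  expect_length(sim$graphs, 10)
  for (g in sim$graphs) {
    expect_true(igraph::is_dag(igraph::graph_from_data_frame(
      pathwayEdges(g)[, 1:2], vertices = data.frame(name = pathwayNodes(g)))))
    expect_true(all(pathwayNodes(g) %in% universe))
    expect_true(validObject(g))
  }
  noInhib <- simulatePathways(
    graphSimulationConfig(nPathways = 5, inhibitionFraction = 0, seed = 75),
    universe)$graphs
  expect_true(all(unlist(lapply(noInhib, function(g)
    pathwayEdges(g)$sign)) == 1))
  # density -> 1 on 5 acyclic nodes approaches the complete DAG (10 edges)
  dense <- simulatePathways(
    graphSimulationConfig(nPathways = 3, sizeRange = c(5, 5),
                          edgeDensity = 0.999, seed = 76), universe)$graphs
  expect_true(all(vapply(dense, function(g) nrow(pathwayEdges(g)), 0) == 10))
  expect_error(graphSimulationConfig(sizeRange = c(2, 5)), "size is 3")
})

test_that("artificial nulls split controls and carry no labels over", {
  ds <- tinyDataset(nGenes = 50, nCase = 4, nControl = 10, seed = 77)
  nulls <- makeArtificialNulls(ds, nSets = 5, seed = 78)
  expect_length(nulls, 5)
  for (n in nulls) {
    expect_equal(ncol(n), 10)            # controls only
    expect_equal(sum(sampleGroups(n) == "case"), 5)
    expect_true(all(colnames(n) %in%
                      colnames(ds)[sampleGroups(ds) == "control"]))
  }
  ds7 <- tinyDataset(nGenes = 20, nCase = 3, nControl = 7, seed = 79)
  n7 <- makeArtificialNulls(ds7, nSets = 1, seed = 80)[[1]]
  expect_equal(as.vector(table(sampleGroups(n7))[c("case", "control")]),
               c(3, 4))
  expect_error(makeArtificialNulls(tinyDataset(nControl = 5), nSets = 1),
               "at least 6")
  s1 <- sampleGroups(makeArtificialNulls(ds, 1, seed = 81)[[1]])
  s2 <- sampleGroups(makeArtificialNulls(ds, 1, seed = 82)[[1]])
  expect_false(identical(s1, s2))
})

test_that("pathway signal injection shifts only the targeted genes", {
  ds <- tinyDataset(nGenes = 60, seed = 83)
  g <- PathwayGraph("p", nodes = rownames(ds)[1:10])
  inj <- injectPathwaySignal(ds, g, effectSize = 2, fraction = 1,
                             seed = 84)
  expect_setequal(attr(inj, "injectedGenes"), rownames(ds)[1:10])
  ci <- which(sampleGroups(ds) == "case")
  expect_equal(exprValues(inj)[1:10, ci],
               exprValues(ds)[1:10, ci] + 2)
  expect_equal(exprValues(inj)[11:60, ], exprValues(ds)[11:60, ])
  same <- injectPathwaySignal(ds, g, effectSize = 0, seed = 85)
  expect_equal(exprValues(same), exprValues(ds))
  # on the intensity scale the shift is a fold change in log2 space
  dsU <- tinyDataset(nGenes = 20, seed = 86, scaled = FALSE)
  gU <- PathwayGraph("p", nodes = rownames(dsU)[1:5])
  injU <- injectPathwaySignal(dsU, gU, effectSize = 1, fraction = 1,
                              seed = 87)
  ciU <- which(sampleGroups(dsU) == "case")
  expect_equal(log2(exprValues(injU)[1:5, ciU] + 1),
               log2(exprValues(dsU)[1:5, ciU] + 1) + 1, tolerance = 1e-12)
  half <- injectPathwaySignal(ds, g, effectSize = 1, fraction = 0.5,
                              seed = 88)
  expect_length(attr(half, "injectedGenes"), 5)
})
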