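test_that("perturbation factors solve the parent-propagation recursion", {
  ab <- PathwayGraph("ab", edges = data.frame(from = "a", to = "b",
                                              sign = 1))
  expect_equal(unclass(perturbationFactors(ab, c(a = 1, b = 0)))[c("a", "b")],
               c(a = 1, b = 1))
  abNeg <- PathwayGraph("ab-", edges = data.frame(from = "a", to = "b",
                                                  sign = -1))
  expect_equal(unclass(perturbationFactors(abNeg, c(a = 1, b = 0)))[c("a", "b")],
               c(a = 1, b = -1))
  zero <- perturbationFactors(chainGraph(), c(a = 0, b = 0, c = 0))
  expect_equal(unname(zero[c("a", "b", "c")]), c(0, 0, 0))
  expect_error(perturbationFactors(ab, c(a = 1)), "every pathway node")
})

test_that("linear solve equals topological forward propagation on DAGs", {
  set.seed(23)
  for (rep in 1:100) {
    g <- randomDag(sample(3:10, 1), pEdge = 0.45)
    delta <- stats::setNames(round(rnorm(length(pathwayNodes(g))), 2),
                             pathwayNodes(g))
    pf <- perturbationFactors(g, delta)
    expect_equal(unclass(pf)[pathwayNodes(g)], oraclePropagate(g, delta),
                 tolerance = 1e-9)
  }
})

test_that("total perturbation is the summed inherited perturbation", {
  expect_equal(totalPerturbation(c(a = 1, b = 1), c(a = 1, b = 0)), 1)
  expect_equal(totalPerturbation(c(a = 1, b = -1), c(a = 1, b = 0)), -1)
  expect_equal(totalPerturbation(c(a = 2, b = 3), c(b = 3, a = 2)), 0)
  expect_error(totalPerturbation(c(a = 1), c(b = 1)), "same genes")
})

test_that("the DE-count tail probability matches brute-force enumeration", {
  expect_equal(pNDE(0, 5, 4, 20), 1)
  expect_equal(pNDE(2, 5, 4, 20), 0.2487, tolerance = 1e-4)
  expect_equal(pNDE(3, 3, 3, 3), 1)
  expect_error(pNDE(5, 3, 4, 20), "impossible")
  set.seed(31)
  for (rep in 1:60) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    nDe <- sample(0:N, 1)
    k <- sample(0:min(K, nDe), 1)
    expect_equal(pNDE(k, K, nDe, N), oracleHyperTail(k, K, nDe, N),
                 tolerance = 1e-12)
  }
})

test_that("perturbation bootstrap p-values match placement enumeration", {
  # chain with one DE value: placements give PB in {2v, v, 0}
  p <- pPB(chainGraph(), c(a = 2, b = 0, c = 0), nBoot = 3000, seed = 11)
  exact <- 2 / 3  # |PB - med| >= |2v - med| holds for 2 of 3 placements
  mcse <- sqrt(exact * (1 - exact) / 3000)
  expect_lt(abs(p - exact), 3 * mcse + 2 / 3001)

  one <- PathwayGraph("one", nodes = "a")
  expect_equal(pPB(one, c(a = 1), nBoot = 200, seed = 1), 1)
  # all placements equivalent in a symmetric star -> p = 1
  expect_equal(pPB(starGraph(), c(a = 0, b = 1, c = 0, d = 0),
                   nBoot = 300, seed = 2), 1)
  expect_warning(p0 <- pPB(chainGraph(), c(a = 0, b = 0, c = 0),
                           nBoot = 200, seed = 3), "zero")
  expect_equal(p0, 1)
  expect_error(pPB(chainGraph(), c(a = 1, b = 0, c = 0), nBoot = 10), ">= 100")
})

test_that("probability combination is the exact closed form and monotone", {
  expect_equal(spiaCombine(1, 1), 1)
  expect_equal(spiaCombine(exp(-1), 1), 2 / exp(1))
  expect_equal(spiaCombine(0.01, 1), 0.01 - 0.01 * log(0.01))
  expect_error(spiaCombine(0, 0.5), "\\(0, 1\\]")
  cs <- 10^seq(-8, 0, length.out = 50)
  vals <- vapply(cs, function(c) spiaCombine(c, 1), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("the pathway-level runner combines both evidence channels", {
  ds <- tinyDataset(nGenes = 200, nCase = 8, nControl = 8, shift = 4,
                    shiftGenes = sprintf("g%03d", 1:8), seed = 41)
  de <- detectDE(ds)
  hot <- PathwayGraph("hot", nodes = sprintf("g%03d", 1:8),
                      edges = data.frame(from = sprintf("g%03d", 1:7),
                                         to = sprintf("g%03d", 2:8),
                                         sign = 1))
  cold <- PathwayGraph("cold", nodes = sprintf("g%03d", 101:110))
  res <- runSpia(list(hot, cold), de, nBoot = 500, seed = 5)
  expect_lt(res$score[res$pathway_id == "hot"],
            res$score[res$pathway_id == "cold"])
  expect_true(all(res$score > 0 & res$score <= 1))
  expect_equal(res$fdr, bhFDR(res$score))
  unmeasured <- PathwayGraph("ghost", nodes = c("nope1", "nope2"))
  expect_warning(runSpia(list(hot, unmeasured), de, nBoot = 200, seed = 1),
                 "skipped")
})
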