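test_that("principal curve recovers a straight line exactly", {
  set.seed(51)
  lam <- scale(rnorm(12))[, 1] * 4
  X <- cbind(2 * lam + 1, -lam + 3)
  pc <- fitPrincipalCurve(X)
  pr <- projectToCurve(pc, X)
  expect_lt(max(pr$dist), 1e-6)
  # two clusters on a line at 0 and 10: arc separation ~ 10
  Y <- rbind(matrix(rnorm(10, 0, 1e-3), 5, 2),
             matrix(rnorm(10, 10, 1e-3), 5, 2))
  pcY <- fitPrincipalCurve(Y)
  prY <- projectToCurve(pcY, Y)
  expect_equal(abs(mean(prY$lambda[6:10]) - mean(prY$lambda[1:5])),
               10 * sqrt(2), tolerance = 0.01)
  expect_error(fitPrincipalCurve(matrix(1, 6, 2)), "degenerate")
  expect_error(fitPrincipalCurve(X[1:3, ]), "at least 5")
})

test_that("principal curve follows a noisy arc within the noise scale", {
  set.seed(52)
  th <- runif(200, 0, pi / 2)
  P <- cbind(10 * cos(th) + rnorm(200, 0, 0.1),
             10 * sin(th) + rnorm(200, 0, 0.1))
  pc <- fitPrincipalCurve(P)
  expect_lt(mean(projectToCurve(pc, P)$dist), 0.3)
})

test_that("deregulation scores are arc distances from the control centroid", {
  # controls on a line through the origin with unit per-gene sd,
  # so control-based standardisation leaves the geometry unchanged
  set.seed(53)
  ctrl <- scale(rnorm(8))[, 1]            # mean 0, sd 1 exactly
  lamCase <- c(5, -2, 1, 0.5) / sqrt(3)   # arc positions spread over 3 genes
  m <- rbind(c(lamCase, ctrl), c(lamCase, ctrl), c(lamCase, ctrl))
  rownames(m) <- c("gA", "gB", "gC")
  colnames(m) <- c(paste0("case", 1:4), paste0("ctrl", 1:8))
  # shift into valid log2 space (positive); standardisation removes it
  ds <- ExpressionDataset(m + 10, rep(c("case", "control"), c(4, 8)),
                          scaled = TRUE)
  # without standardisation the scores are the raw arc distances
  sc0 <- pathifierScores(ds, c("gA", "gB", "gC"), standardize = FALSE)
  expect_equal(sc0$score[1:4], c(5, 2, 1, 0.5), tolerance = 1e-6)
  # the default z-scoring rescales the collinear cloud by the per-gene sd
  s <- sd(c(lamCase, ctrl))
  sc <- pathifierScores(ds, c("gA", "gB", "gC"))
  expect_equal(sc$score[1:4], c(5, 2, 1, 0.5) / s, tolerance = 1e-6)
  # the sample sitting at the control centroid scores 0
  m2 <- m; m2[, "case4"] <- 0
  ds2 <- ExpressionDataset(m2 + 10, rep(c("case", "control"), c(4, 8)),
                           scaled = TRUE)
  expect_lt(pathifierScores(ds2, c("gA", "gB", "gC"))$score[4], 1e-8)
})

test_that("scores ignore sample order and rigid rotations", {
  ds <- tinyDataset(nGenes = 12, nCase = 6, nControl = 8, seed = 54)
  sc <- pathifierScores(ds, rownames(ds)[1:5], standardize = FALSE)
  perm <- sample(ncol(ds))
  dsPerm <- ExpressionDataset(exprValues(ds)[, perm],
                              sampleGroups(ds)[perm], scaled = TRUE)
  scPerm <- pathifierScores(dsPerm, rownames(ds)[1:5],
                            standardize = FALSE)
  expect_equal(scPerm$score[match(sc$sample_id, scPerm$sample_id)],
               sc$score, tolerance = 1e-8)
  # rigid rotation of the reduced cloud leaves arc distances unchanged
  set.seed(55)
  genes <- rownames(ds)[1:4]
  X <- exprValues(ds)[genes, ]
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  Xrot <- Q %*% X
  dimnames(Xrot) <- dimnames(X)
  dsRot <- ExpressionDataset(Xrot, sampleGroups(ds), scaled = TRUE)
  scRot <- pathifierScores(dsRot, genes, standardize = FALSE)
  sc0 <- pathifierScores(ds, genes, standardize = FALSE)
  expect_equal(scRot$score, sc0$score, tolerance = 1e-6)
})

test_that("control-count and gene-count preconditions are enforced", {
  ds3 <- tinyDataset(nGenes = 10, nCase = 5, nControl = 3, seed = 56)
  expect_error(pathifierScores(ds3, rownames(ds3)[1:5]), "4 control")
  ds <- tinyDataset(nGenes = 10, seed = 57)
  expect_error(pathifierScores(ds, rownames(ds)[1:2]), "3 pathway genes")
  expect_error(pathifierScores(tinyDataset(scaled = FALSE, seed = 58),
                               rownames(ds)[1:5]), "scaled")
})

test_that("the group-level conversion flags shifted score distributions", {
  set.seed(59)
  mk <- function(shift) {
    data.frame(sample_id = sprintf("s%02d", 1:16),
               group = rep(c("case", "control"), each = 8),
               score = c(rnorm(8, shift), rnorm(8)))
  }
  res <- pathifierGroupTest(list(p1 = mk(10), p2 = mk(0)))
  expect_lt(res$fdr[res$pathway_id == "p1"], 0.05)
  expect_equal(res$method, rep("Pathifier", 2))
  single <- pathifierGroupTest(list(only = mk(1)))
  expect_equal(single$fdr, single$p_value)  # BH with one pathway
  # calibrated under identical distributions
  reps <- replicate(40, pathifierGroupTest(list(p = mk(0)))$p_value)
  expect_gt(mean(reps), 0.3)
  expect_gt(mean(reps < 0.5), 0.25)
})
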