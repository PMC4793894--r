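test_that("signed edge-list files are parsed into pathway graphs", {
  f <- withr::local_tempfile()
  writeLines(c("# comment", "P1 | a activation b", "P1 | b inhibition c",
               "P2 | x activation y", "P2 | node z"), f)
  gs <- readPathwayGraphs(f)
  expect_length(gs, 2)
  expect_setequal(pathwayNodes(gs[[1]]), c("a", "b", "c"))
  e <- pathwayEdges(gs[[1]])
  expect_equal(e$sign[e$from == "a"], 1)
  expect_equal(e$sign[e$from == "b"], -1)
  expect_true("z" %in% pathwayNodes(gs[[2]]))

  empty <- withr::local_tempfile()
  writeLines(character(), empty)
  expect_length(readPathwayGraphs(empty), 0)

  bad <- withr::local_tempfile()
  writeLines("P1 | a sometimes b", bad)
  expect_error(readPathwayGraphs(bad), "unknown interaction")
  bad2 <- withr::local_tempfile()
  writeLines("no pipe here", bad2)
  expect_error(readPathwayGraphs(bad2), "line 1")
})

test_that("pathway graph round-trips through the edge-list writer", {
  gs <- list(chainGraph(c(1, -1)),
             PathwayGraph("iso", nodes = c("u", "v")))
  f <- withr::local_tempfile()
  writePathwayGraphs(gs, f)
  back <- readPathwayGraphs(f)
  expect_equal(pathwayEdges(back[[1]]), pathwayEdges(gs[[1]]))
  expect_setequal(pathwayNodes(back[[2]]), c("u", "v"))
})

test_that("graph validity rejects bad edges", {
  expect_error(new("PathwayGraph", id = "x", name = "x", nodes = c("a"),
                   edges = data.frame(from = "a", to = "b", sign = 1)),
               "declared node")
  expect_error(PathwayGraph("x", edges = data.frame(from = "a", to = "b",
                                                    sign = 2)),
               "sign")
  expect_error(PathwayGraph("x", edges = data.frame(from = c("a", "a"),
                                                    to = c("b", "b"),
                                                    sign = c(1, -1))),
               "duplicate")
})

test_that("GMT files are read with dedup warning and field validation", {
  f <- withr::local_tempfile()
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tdesc2\tg3\tg3"), f)
  expect_warning(gsc <- readGMT(f), "duplicate")
  expect_equal(gsc[["S1"]], c("g1", "g2"))
  expect_equal(gsc[["S2"]], "g3")
  bad <- withr::local_tempfile()
  writeLines("S1\tdesc", bad)
  expect_error(readGMT(bad), "3 tab-separated")
})

test_that("the six centralities match hand-enumerated values", {
  cc <- centralities(chainGraph())
  expect_equal(cc$equal.weight, c(1, 1, 1))
  expect_equal(cc$out.reach, c(2, 1, 0))
  expect_equal(cc$in.reach, c(0, 1, 2))
  expect_equal(cc$in.degree, c(0, 1, 1))
  expect_equal(cc$betweenness, c(0, 1, 0))

  iso <- centralities(PathwayGraph("one", nodes = "a"))
  expect_equal(unlist(iso[1, -1]),
               c(equal.weight = 1, in.degree = 0, out.degree = 0,
                 betweenness = 0, in.reach = 0, out.reach = 0))

  st <- centralities(starGraph())
  expect_equal(st$out.degree[st$node == "a"], 3)
  expect_equal(st$betweenness, rep(0, 4))
})

test_that("leaf/root reach is zero and centralities are label-invariant", {
  set.seed(11)
  for (rep in 1:20) {
    g <- randomDag(sample(4:8, 1))
    cc <- centralities(g)
    leaves <- cc$node[cc$out.degree == 0]
    roots <- cc$node[cc$in.degree == 0]
    expect_true(all(cc$out.reach[cc$node %in% leaves] == 0))
    expect_true(all(cc$in.reach[cc$node %in% roots] == 0))
    # relabel nodes by a random permutation of fresh names
    newNames <- stats::setNames(
      sample(LETTERS, length(pathwayNodes(g))), pathwayNodes(g))
    e <- pathwayEdges(g)
    g2 <- PathwayGraph("relab", nodes = unname(newNames[pathwayNodes(g)]),
                       edges = data.frame(from = unname(newNames[e$from]),
                                          to = unname(newNames[e$to]),
                                          sign = e$sign))
    cc2 <- centralities(g2)
    expect_equal(cc2[match(newNames[cc$node], cc2$node), -1], cc[, -1],
                 ignore_attr = TRUE)
  }
})

test_that("influence matrix matches hand inverses and path sums", {
  ab <- PathwayGraph("ab", edges = data.frame(from = "a", to = "b",
                                              sign = 1))
  expect_equal(influenceMatrix(ab),
               matrix(c(1, 1, 0, 1), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  none <- PathwayGraph("none", nodes = c("a", "b"))
  expect_equal(unname(influenceMatrix(none)), diag(2))
  expect_equal(influenceMatrix(chainGraph(c(1, -1)))["c", "a"], -1)
})

test_that("on DAGs the influence matrix equals exhaustive path sums", {
  set.seed(7)
  for (rep in 1:15) {
    g <- randomDag(sample(4:8, 1), pEdge = 0.5)
    expect_equal(influenceMatrix(g, damping = 1), oraclePathSum(g),
                 tolerance = 1e-10)
  }
})

test_that("cyclic influence uses damping and flags singular systems", {
  cyc <- PathwayGraph("cyc", edges = data.frame(from = c("a", "b"),
                                                to = c("b", "a"),
                                                sign = 1))
  L <- influenceMatrix(cyc)  # damping 0.9 applied against spectral radius
  expect_true(all(is.finite(L)))
  expect_error(influenceMatrix(cyc, damping = 1), "smaller damping")
})
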