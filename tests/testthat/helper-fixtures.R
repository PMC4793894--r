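# Shared fixtures built in code.

chainGraph <- function(signs = c(1, 1)) {
  PathwayGraph("chain",
               edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                  sign = signs))
}

starGraph <- function() {
  PathwayGraph("star",
               edges = data.frame(from = "a", to = c("b", "c", "d"),
                                  sign = 1))
}

# Tiny two-group dataset with optional shifted genes.
tinyDataset <- function(nGenes = 50, nCase = 5, nControl = 5, shift = 0,
                        shiftGenes = character(), seed = 1,
                        scaled = TRUE) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(nGenes))
  m <- matrix(rnorm(nGenes * (nCase + nControl), 8, 1), nGenes,
              dimnames = list(genes, c(sprintf("c%02d", seq_len(nCase)),
                                       sprintf("r%02d", seq_len(nControl)))))
  m[shiftGenes, seq_len(nCase)] <- m[shiftGenes, seq_len(nCase)] + shift
  if (!scaled) m <- pmax(2^m - 1, 0)
  ExpressionDataset(m, rep(c("case", "control"), c(nCase, nControl)),
                    scaled = scaled)
}

# Random DAG over letters, for oracle-equivalence loops.
randomDag <- function(nNodes, pEdge = 0.4) {
  nodes <- letters[seq_len(nNodes)]
  pairs <- which(upper.tri(matrix(TRUE, nNodes, nNodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < pEdge
  e <- pairs[keep, , drop = FALSE]
  PathwayGraph("dag", nodes = nodes,
               edges = data.frame(from = nodes[e[, 1]], to = nodes[e[, 2]],
                                  sign = sample(c(-1, 1), sum(keep),
                                                replace = TRUE)))
}
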