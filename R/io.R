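# File readers/writers for the plain-text interchange formats.

#' Read signed pathway graphs from an edge-list file
#'
#' Parses the SIF-like dialect `pathway_id | source interaction target`,
#' with `interaction` either `activation` (+1) or `inhibition` (-1), and
#' optional `pathway_id | node <gene>` lines declaring isolated nodes.
#' Fields are tab- or space-separated; lines starting with `#` and blank
#' lines are ignored.
#'
#' @param path path to the edge-list file.
#' @return A list of [PathwayGraph-class] objects, one per pathway id, in
#'   order of first appearance.
#' @examples
#' f <- tempfile()
#' writeLines(c("P1 | a activation b", "P1 | b inhibition c"), f)
#' readPathwayGraphs(f)[[1]]
#' @export
readPathwayGraphs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character()
  nodes <- list(); edges <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    parts <- strsplit(raw, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: expected 'pathway_id | ...', got %s",
                   ln, sQuote(raw)))
    pid <- trimws(parts[1])
    toks <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (!pid %in% ids) {
      ids <- c(ids, pid)
      nodes[[pid]] <- character()
      edges[[pid]] <- list()
    }
    if (length(toks) == 2L && toks[1] == "node") {
      nodes[[pid]] <- c(nodes[[pid]], toks[2])
    } else if (length(toks) == 3L) {
      sgn <- switch(toks[2], activation = 1, inhibition = -1,
                    stop(sprintf("line %d: unknown interaction %s",
                                 ln, sQuote(toks[2]))))
      edges[[pid]][[length(edges[[pid]]) + 1L]] <-
        list(from = toks[1], to = toks[3], sign = sgn)
    } else {
      stop(sprintf("line %d: malformed entry %s", ln, sQuote(raw)))
    }
  }
  lapply(ids, function(pid) {
    e <- edges[[pid]]
    ed <- if (length(e))
      data.frame(from = vapply(e, `[[`, "", "from"),
                 to = vapply(e, `[[`, "", "to"),
                 sign = vapply(e, `[[`, 0, "sign"))
    else data.frame(from = character(), to = character(), sign = numeric())
    PathwayGraph(pid, nodes = nodes[[pid]], edges = ed)
  })
}

#' Write pathway graphs in the signed edge-list dialect
#'
#' @param graphs list of [PathwayGraph-class] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePathwayGraphs <- function(graphs, path) {
  out <- unlist(lapply(graphs, function(g) {
    e <- pathwayEdges(g)
    lines <- if (nrow(e))
      sprintf("%s | %s %s %s", g@id, e$from,
              ifelse(e$sign > 0, "activation", "inhibition"), e$to)
    else character()
    iso <- setdiff(pathwayNodes(g), c(e$from, e$to))
    c(lines, if (length(iso)) sprintf("%s | node %s", g@id, iso))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Duplicate genes within a line are dropped with a warning.
#'
#' @param path path to the GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("line %d: GMT lines need >= 3 tab-separated fields", ln))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("set '%s': duplicate gene ids removed", f[1]))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    descs <- c(descs, f[2])
  }
  GeneSetCollection(sets, setNames = descs)
}

#' Write a gene-set collection to GMT
#'
#' @param gsc a [GeneSetCollection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(gsc, path) {
  nm <- gsc@setNames
  writeLines(vapply(seq_along(gsc@sets), function(i)
    paste(c(names(gsc@sets)[i], nm[i], gsc@sets[[i]]), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Flatten pathway graphs into a gene-set collection
#'
#' @param graphs list of [PathwayGraph-class] objects.
#' @return A [GeneSetCollection-class] with one set per pathway (node sets).
#' @export
asGeneSetCollection <- function(graphs) {
  sets <- lapply(graphs, pathwayNodes)
  names(sets) <- vapply(graphs, function(g) g@id, "")
  GeneSetCollection(sets, setNames = vapply(graphs, function(g) g@name, ""))
}

#' Read an expression matrix with sample labels
#'
#' The matrix file is TSV with gene/probe ids in the first column and a
#' header of sample ids; the labels file is TSV with columns `sample_id`
#' and `group` (values `case`/`control`).
#'
#' @param matrixPath path to the expression TSV.
#' @param labelsPath path to the labels TSV.
#' @param scaled whether the stored values are log2(x + 1) scaled.
#' @return An [ExpressionDataset-class].
#' @export
readExpressionDataset <- function(matrixPath, labelsPath, scaled = FALSE) {
  m <- read.delim(matrixPath, check.names = FALSE)
  values <- as.matrix(m[, -1, drop = FALSE])
  rownames(values) <- as.character(m[[1]])
  lab <- read.delim(labelsPath, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(lab)))
    stop("labels file needs columns 'sample_id' and 'group': ", labelsPath)
  groups <- stats::setNames(as.character(lab$group), lab$sample_id)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  ExpressionDataset(values, groups[colnames(values)], scaled = scaled)
}

#' Write an expression dataset as matrix + labels TSVs
#'
#' @param ds an [ExpressionDataset-class].
#' @param matrixPath,labelsPath output paths.
#' @return `matrixPath`, invisibly.
#' @export
writeExpressionDataset <- function(ds, matrixPath, labelsPath) {
  df <- data.frame(gene_id = rownames(ds), exprValues(ds),
                   check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(ds),
                         group = sampleGroups(ds)),
              labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' Write a combined per-pathway results table
#'
#' Rows are sorted by `(method, fdr, pathway_id)` so reruns with the same
#' seed are byte-identical.
#'
#' @param results data.frame with columns `pathway_id`, `method`, `score`,
#'   `p_value`, `fdr`, `significant` and optionally `extras`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(results, path) {
  if (!"extras" %in% colnames(results)) results$extras <- ""
  ord <- order(results$method, results$fdr, results$pathway_id)
  cols <- c("pathway_id", "method", "score", "p_value", "fdr",
            "significant", "extras")
  write.table(results[ord, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
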