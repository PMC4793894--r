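# Principal-curve deregulation scoring per sample (Pathifier-style).

#' Fit a principal curve by projection/smoothing iteration
#'
#' Hastie-Stuetzle iteration: the curve is initialised on the first
#' principal-component segment; then the algorithm alternates (a)
#' projecting the points onto the current polyline, (b) ordering them by
#' projection parameter, (c) smoothing each coordinate against the
#' parameter with a locally weighted averaging smoother ([stats::lowess],
#' `iter = 0`) of the given span, and (d) reparameterising by cumulative
#' arc length. Iteration stops when the mean squared projection distance
#' changes by less than `tol` (or immediately when the initial segment
#' already interpolates the cloud, as for exactly collinear data) or after
#' `maxIter` rounds.
#'
#' @param points numeric matrix, samples x dimensions (>= 5 points, >= 2
#'   dimensions).
#' @param span smoother span as a fraction of the points (default 0.75).
#' @param maxIter maximum iterations (default 10).
#' @param tol convergence tolerance on the mean squared projection
#'   distance (default 1e-4).
#' @return A [PrincipalCurve-class].
#' @export
fitPrincipalCurve <- function(points, span = 0.75, maxIter = 10,
                              tol = 1e-4) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 5L) stop("need at least 5 points")
  if (ncol(points) < 2L) stop("need at least 2 dimensions")
  mu <- colMeans(points)
  Xc <- sweep(points, 2, mu)
  if (max(abs(Xc)) < 1e-12) stop("degenerate cloud: all points identical")
  v1 <- svd(Xc, nu = 0, nv = 1)$v[, 1]
  lam <- drop(Xc %*% v1)
  ord <- order(lam)
  poly <- sweep(outer(lam[ord], v1), 2, mu, `+`)
  poly <- .dedupPolyline(poly)
  curve <- list(polyline = poly, arc = .arcLengths(poly))
  proj <- .projectPolyline(curve, points)
  msd <- mean(proj$dist2)
  iter <- 0L
  converged <- msd <= 1e-12
  while (!converged && iter < maxIter) {
    iter <- iter + 1L
    ord <- order(proj$lambda)
    lamSorted <- proj$lambda[ord]
    smoothed <- vapply(seq_len(ncol(points)), function(j)
      lowess(lamSorted, points[ord, j], f = span, iter = 0)$y,
      numeric(n))
    poly <- .dedupPolyline(matrix(smoothed, nrow = n))
    if (nrow(poly) < 2L) break  # curve collapsed to a point
    curve <- list(polyline = poly, arc = .arcLengths(poly))
    proj <- .projectPolyline(curve, points)
    msdNew <- mean(proj$dist2)
    converged <- abs(msd - msdNew) < tol
    msd <- msdNew
  }
  new("PrincipalCurve", polyline = curve$polyline, arcLength = curve$arc,
      iterations = iter, msd = msd, converged = converged || msd <= 1e-12)
}

.arcLengths <- function(poly) {
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                       poly[-nrow(poly), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

.dedupPolyline <- function(poly) {
  if (nrow(poly) < 2L) return(poly)
  seg <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                       poly[-nrow(poly), , drop = FALSE])^2))
  poly[c(TRUE, seg > 1e-12), , drop = FALSE]
}

# Orthogonal projection of points onto a polyline; returns per point the
# arc-length parameter lambda and the squared distance.
.projectPolyline <- function(curve, points) {
  poly <- curve$polyline; arc <- curve$arc
  nSeg <- nrow(poly) - 1L
  n <- nrow(points)
  bestD2 <- rep(Inf, n)
  bestLam <- rep(0, n)
  for (s in seq_len(nSeg)) {
    a <- poly[s, ]; d <- poly[s + 1L, ] - a
    len2 <- sum(d^2)
    W <- sweep(points, 2, a)
    t <- pmin(pmax(drop(W %*% d) / len2, 0), 1)
    d2 <- rowSums((W - outer(t, d))^2)
    upd <- d2 < bestD2
    bestD2[upd] <- d2[upd]
    bestLam[upd] <- arc[s] + t[upd] * sqrt(len2)
  }
  list(lambda = bestLam, dist2 = bestD2)
}

#' Project new points onto a fitted principal curve
#'
#' @param curve a [PrincipalCurve-class].
#' @param points numeric matrix, samples x dimensions.
#' @return data.frame with `lambda` (arc-length position of the
#'   projection) and `dist` (Euclidean distance to the curve).
#' @export
projectToCurve <- function(curve, points) {
  pr <- .projectPolyline(list(polyline = curve@polyline,
                              arc = curve@arcLength), as.matrix(points))
  data.frame(lambda = pr$lambda, dist = sqrt(pr$dist2))
}

#' Per-sample pathway deregulation scores along a principal curve
#'
#' Samples are reduced to the pathway's measured genes, each gene
#' standardised (z-scored over all samples, making distances comparable
#' across genes), and a principal curve is fitted through all reduced
#' samples. A sample's deregulation score is the arc-length distance
#' along the curve between its projection and the projection of the
#' control centroid, so the control centroid scores 0 by construction.
#' Standardising over all samples (rather than controls only) keeps the
#' case and control clouds exchangeable under the null; control-only
#' standardisation at typical sample sizes imprints a systematic offset
#' on the case cloud and inflates false-positive group calls.
#'
#' @param ds a scaled [ExpressionDataset-class] with at least 4 control
#'   samples (principal-curve fitting through fewer controls is not
#'   supported; with only three controls the control centroid is too
#'   poorly determined).
#' @param geneSet character vector of pathway gene ids (>= 3 must be
#'   measured).
#' @param span,maxIter,tol passed to [fitPrincipalCurve()].
#' @param standardize z-score each gene over all samples before fitting
#'   (default TRUE; constant genes fall back to sd 1).
#' @return data.frame with `sample_id`, `group`, `score`, plus attributes
#'   `curve` (the [PrincipalCurve-class]) and `centroidLambda`.
#' @export
pathifierScores <- function(ds, geneSet, span = 0.75, maxIter = 10,
                            tol = 1e-4, standardize = TRUE) {
  if (!isScaled(ds))
    stop("deregulation scoring expects log2(x + 1) scaled input")
  ri <- .controlIdx(ds)
  if (length(ri) < 4L)
    stop("at least 4 control samples are required for curve fitting")
  genes <- intersect(geneSet, rownames(ds))
  if (length(genes) < 3L) stop("fewer than 3 pathway genes are measured")
  X <- t(exprValues(ds)[genes, , drop = FALSE])  # samples x genes
  if (standardize) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    sdv[sdv < 1e-8] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  }
  curve <- fitPrincipalCurve(X, span = span, maxIter = maxIter, tol = tol)
  proj <- projectToCurve(curve, X)
  centroid <- colMeans(X[ri, , drop = FALSE])
  lam0 <- projectToCurve(curve, matrix(centroid, 1))$lambda
  out <- data.frame(sample_id = colnames(ds), group = sampleGroups(ds),
                    score = abs(proj$lambda - lam0), row.names = NULL)
  attr(out, "curve") <- curve
  attr(out, "centroidLambda") <- lam0
  out
}

#' Group-level test on per-sample deregulation scores
#'
#' Converts sample-level scores to one pathway-level call: a two-sided
#' Welch t-test of case versus control scores per pathway, then FDR
#' across pathways with [bhFDR()].
#'
#' @param scoreTables named list of score tables from [pathifierScores()]
#'   (names = pathway ids), each with >= 2 samples per group.
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return data.frame with `pathway_id`, `method`, `score` (mean case
#'   score minus mean control score), `p_value`, `fdr`, `significant`.
#' @export
pathifierGroupTest <- function(scoreTables, fdrThreshold = 0.05) {
  rows <- lapply(names(scoreTables), function(id) {
    st <- scoreTables[[id]]
    x <- st$score[st$group == "case"]
    y <- st$score[st$group == "control"]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("pathway '%s': need >= 2 scores per group", id))
    wt <- .welchDetector(matrix(st$score, nrow = 1),
                         which(st$group == "case"),
                         which(st$group == "control"))
    data.frame(pathway_id = id, score = wt$delta, p_value = wt$pvalue)
  })
  res <- do.call(rbind, rows)
  res$method <- "Pathifier"
  res$fdr <- bhFDR(res$p_value)
  res$significant <- res$fdr < fdrThreshold
  res[, c("pathway_id", "method", "score", "p_value", "fdr", "significant")]
}
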