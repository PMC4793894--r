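# Cross-dataset consistency scoring with a false-positive penalty.

#' Count pathways found in exactly h of l data sets
#'
#' @param sigSets list of length `l`; each element a character vector of
#'   significant pathway ids for one data set.
#' @param l number of data sets (defaults to `length(sigSets)`).
#' @return named integer vector `beta[h]` for `h = ceiling(l/2) .. l`:
#'   the number of pathways significant in exactly `h` data sets.
#'   Pathways found in fewer than a majority of the data sets never enter.
#' @export
betaCounts <- function(sigSets, l = length(sigSets)) {
  if (length(sigSets) != l) stop("'sigSets' must have length l")
  hMin <- ceiling(l / 2)
  counts <- table(unlist(lapply(sigSets, unique)))
  vapply(stats::setNames(hMin:l, hMin:l),
         function(h) sum(counts == h), 0L)
}

#' Mean number of false-positive pathways on artificial data
#'
#' @param artificialSigSets nonempty list of character vectors: the
#'   significant pathways a method reported on each artificial null data
#'   set.
#' @return numeric(1): the mean significant-set size (may be fractional).
#' @export
alphaMean <- function(artificialSigSets) {
  if (!length(artificialSigSets)) stop("need at least one artificial set")
  mean(lengths(artificialSigSets))
}

#' Cross-dataset consistency score
#'
#' Scores a method's outcome over `l` real data sets and a batch of
#' artificial null data sets as
#' \deqn{score = \frac{1000}{T} \sum_{h=\lceil l/2 \rceil}^{l}
#'   \frac{\beta(h) (h - \lceil l/2 \rceil + 1)^2}{(\alpha + 1)^2},}
#' where \eqn{\beta(h)} counts pathways significant in exactly `h` real
#' data sets, \eqn{\alpha} is the mean number of significant pathways on
#' the artificial sets (false positives; the +1 avoids division by zero),
#' and \eqn{T = P (l - \lceil l/2 \rceil + 1)^2} is the theoretical
#' maximum, making scores comparable across studies with different `l`.
#' The factor 1000 keeps typical values readable; the score lives in
#' \[0, 1000\] and attains 1000 exactly when every tested pathway is found
#' in every real data set with no false positives.
#'
#' @param sigSets list of significant-pathway id vectors, one per real
#'   data set (`l = length(sigSets)`, must be >= 2).
#' @param artificialSigSets list of significant-pathway id vectors over
#'   the artificial data sets; an empty list means `alpha = 0`.
#' @param nPathways P, the number of tested pathways (>= 1).
#' @param method optional method label carried into the report.
#' @return one-row data.frame: `method`, `score`, `alpha`, `T`, `P`, `l`,
#'   plus `beta.<h>` columns for `h = ceiling(l/2) .. l`.
#' @examples
#' consistencyScore(list(c("p1"), c("p1"), character(), character(),
#'                       character(), character()),
#'                  list(), nPathways = 86)
#' @export
consistencyScore <- function(sigSets, artificialSigSets = list(),
                             nPathways, method = NA_character_) {
  l <- length(sigSets)
  if (l < 2) stop("need at least two real data sets")
  if (nPathways < 1) stop("'nPathways' must be >= 1")
  beta <- betaCounts(sigSets, l)
  if (any(beta > nPathways))
    stop("beta counts exceed the number of tested pathways")
  alpha <- if (length(artificialSigSets)) alphaMean(artificialSigSets) else 0
  hMin <- ceiling(l / 2)
  h <- hMin:l
  Tmax <- nPathways * (l - hMin + 1)^2
  score <- 1000 / Tmax * sum(beta * (h - hMin + 1)^2 / (alpha + 1)^2)
  out <- data.frame(method = method, score = score, alpha = alpha,
                    T = Tmax, P = nPathways, l = l)
  for (i in seq_along(h)) out[[paste0("beta.", h[i])]] <- beta[i]
  out
}
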