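## Majority-voting fusion of the filtered supervised map with the
## unsupervised segmentation, and rendering of the three-maximum-density
## (TMD) map.

#' Per-cluster class densities
#'
#' For each cluster of the segmentation, the fraction of its pixels whose
#' most-probable supervised class is each tissue class (argmax ties break
#' toward the lowest class code). With `soft = TRUE` the per-pixel
#' probability vectors are averaged instead of hard argmax counts.
#'
#' @param seg a [SegmentationMap-class].
#' @param probs a [ProbabilityMap-class] over the same grid (typically the
#'   k-NN filtered map).
#' @param soft average soft probabilities instead of counting argmax labels
#'   (default `FALSE`).
#' @return A [ClusterDensities-class] (rows sum to 1).
#' @export
classDensities <- function(seg, probs, soft = FALSE) {
  stopifnot(is(seg, "SegmentationMap"), is(probs, "ProbabilityMap"))
  d <- dim(probs@probs)
  if (!identical(dim(seg@clusterId), d[1:2])) {
    stop("segmentation and probability map shapes disagree")
  }
  ids <- as.vector(seg@clusterId)
  nclass <- d[3]
  if (soft) {
    pm <- matrix(probs@probs, d[1] * d[2], nclass)
    dens <- rowsum(pm, ids)
  } else {
    am <- as.vector(argmaxMap(probs))
    am_idx <- match(am, probs@classOrder)
    dens <- matrix(0, seg@K, nclass)
    tab <- table(factor(ids, levels = seq_len(seg@K)),
                 factor(am_idx, levels = seq_len(nclass)))
    dens[] <- as.numeric(tab)
  }
  dens <- dens / rowSums(dens)
  new("ClusterDensities", densities = dens,
      classOrder = probs@classOrder)
}

#' Majority vote per cluster
#'
#' Assigns every cluster its maximum-density class. Exact density ties
#' break by the clinically conservative priority
#' tumor > vessel > normal > background (missing tumor is the costly
#' error).
#'
#' @param dens a [ClusterDensities-class].
#' @return Integer vector of class codes, one per cluster.
#' @export
majorityVote <- function(dens) {
  stopifnot(is(dens, "ClusterDensities"))
  pr <- .votePriority()
  # column order by priority; max.col "first" then favors higher priority
  prio_idx <- match(pr[pr %in% dens@classOrder], dens@classOrder)
  m <- dens@densities[, prio_idx, drop = FALSE]
  dens@classOrder[prio_idx[max.col(m, ties.method = "first")]]
}

#' Vote map: per-pixel majority-vote classes
#'
#' Convenience expansion of [majorityVote()] back onto the pixel grid.
#'
#' @param seg a [SegmentationMap-class].
#' @param votes integer class codes per cluster (from [majorityVote()]).
#' @return rows x cols integer matrix of class codes.
#' @export
voteMap <- function(seg, votes) {
  matrix(votes[as.vector(seg@clusterId)], nrow(seg@clusterId),
         ncol(seg@clusterId))
}

#' Render the three-maximum-density (TMD) map
#'
#' For each cluster, the three largest class densities are kept,
#' renormalized to sum 1, and blended as a convex combination of the class
#' colors; every pixel of the cluster is filled with the resulting color.
#' Pure clusters therefore render in the pure class color (tumor red,
#' normal green, vessel blue, background black/white).
#'
#' @param seg a [SegmentationMap-class].
#' @param dens a [ClusterDensities-class].
#' @param colors class-color matrix as returned by [classColors()]; it
#'   must contain a row for every class present in `dens`.
#' @return A [TMDMap-class].
#' @export
renderTMD <- function(seg, dens, colors = classColors()) {
  stopifnot(is(seg, "SegmentationMap"), is(dens, "ClusterDensities"))
  codes <- .tissueCodes()
  class_names <- names(codes)[match(dens@classOrder, codes)]
  if (anyNA(class_names) || !all(class_names %in% rownames(colors))) {
    stop("color table is missing a class present in the densities")
  }
  cmat <- colors[class_names, , drop = FALSE]
  K <- nrow(dens@densities)
  cluster_rgb <- matrix(0, K, 3)
  for (k in seq_len(K)) {
    dv <- dens@densities[k, ]
    top <- order(dv, decreasing = TRUE)[seq_len(min(3L, length(dv)))]
    w <- dv[top]
    if (sum(w) == 0) w <- rep(1, length(top))
    w <- w / sum(w)
    cluster_rgb[k, ] <- colSums(w * cmat[top, , drop = FALSE])
  }
  ids <- as.vector(seg@clusterId)
  d <- dim(seg@clusterId)
  rgb <- array(cluster_rgb[ids, ], c(d[1], d[2], 3))
  rgb[rgb < 0] <- 0
  rgb[rgb > 1] <- 1
  new("TMDMap", rgb = rgb, colors = cmat)
}
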