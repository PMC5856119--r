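## Unsupervised segmentation: bisecting (hierarchical) K-means over pixel
## spectra, splitting the cluster with the largest within-cluster sum of
## squares until K clusters exist.

# within-cluster sum of squares of a row subset
.wcss <- function(x) {
  if (nrow(x) < 2L) return(0)
  mu <- colMeans(x)
  sum(sweep(x, 2, mu)^2)
}

# 2-means with restarts; initial centers drawn from distinct unique rows
# so stats::kmeans never sees duplicated centers
.twoMeans <- function(x, restarts = 10L) {
  ux <- unique(x)
  if (nrow(ux) < 2L) stop("cannot bisect a cluster with < 2 distinct spectra")
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- ux[sample(nrow(ux), 2L), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(kmeans(x, centers = ctr, iter.max = 50L)),
      error = function(e) NULL
    )
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("2-means failed on every restart")
  best$cluster
}

#' Hierarchical (bisecting) K-means segmentation
#'
#' Segments a cube into K spectrally homogeneous clusters: starting from a
#' single cluster holding every pixel spectrum, the cluster with the
#' largest within-cluster sum of squares is repeatedly split by 2-means
#' (10 restarts per split) until K clusters exist. Deterministic given
#' `seed`.
#'
#' @param cube a [HyperCube-class] (typically pre-processed).
#' @param K number of clusters, `1 <= K <= rows * cols` (default 24).
#' @param seed RNG seed for the 2-means restarts.
#' @return A [SegmentationMap-class].
#' @export
hierarchicalKmeans <- function(cube, K = 24L, seed = 1L) {
  stopifnot(is(cube, "HyperCube"))
  x <- .pixelMatrix(cube)
  n <- nrow(x)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the pixel count")
  assign <- rep(1L, n)
  if (K > 1L) {
    withr::with_seed(seed, {
      wcss <- c(.wcss(x))
      distinct <- c(nrow(unique(x)))
      while (max(assign) < K) {
        splittable <- which(distinct >= 2L)
        if (!length(splittable)) {
          stop(sprintf(
            "cannot form %d clusters: only %d distinct spectra", K,
            sum(distinct)
          ))
        }
        target <- splittable[which.max(wcss[splittable])]
        idx <- which(assign == target)
        part <- .twoMeans(x[idx, , drop = FALSE])
        new_id <- max(assign) + 1L
        assign[idx[part == 2L]] <- new_id
        for (id in c(target, new_id)) {
          sub <- x[assign == id, , drop = FALSE]
          wcss[id] <- .wcss(sub)
          distinct[id] <- nrow(unique(sub))
        }
      }
    })
  }
  d <- dim(cube@data)
  SegmentationMap(matrix(assign, d[1], d[2]), K = K)
}

#' Per-cluster pixel counts
#'
#' @param seg a [SegmentationMap-class].
#' @return Integer vector of length K (named by cluster id); sums to the
#'   pixel count.
#' @export
clusterSizes <- function(seg) {
  stopifnot(is(seg, "SegmentationMap"))
  setNames(tabulate(seg@clusterId, nbins = seg@K), seq_len(seg@K))
}

# total within-cluster sum of squares of a segmentation over a cube
.segmentationWCSS <- function(cube, seg) {
  x <- .pixelMatrix(cube)
  ids <- as.vector(seg@clusterId)
  sum(vapply(seq_len(seg@K),
             function(k) .wcss(x[ids == k, , drop = FALSE]), numeric(1)))
}
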