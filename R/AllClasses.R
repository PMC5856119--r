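#' HyperCube: a hyperspectral image cube
#'
#' A rows x cols x bands array of finite values (raw digital numbers,
#' percent reflectance, or pre-processed/standardized signatures) with a
#' strictly increasing wavelength axis in
#' nanometres. Pixels are indexed `(row, col, band)`, 1-based, origin at the
#' top-left of the scene.
#'
#' @slot data numeric array, rows x cols x bands.
#' @slot wavelengths numeric vector of band-centre wavelengths (nm).
#' @slot units `"raw"` or `"reflectance_percent"`.
#' @slot name free-text identifier.
#'
#' @aliases HyperCube-class
#' @export
setClass("HyperCube",
  representation(
    data = "array",
    wavelengths = "numeric",
    units = "character",
    name = "character"
  ),
  prototype(units = "raw", name = "")
)

setValidity("HyperCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) {
    return("data must be a 3-D rows x cols x bands array")
  }
  if (d[1] < 1L || d[2] < 1L || d[3] < 2L) {
    return("cube must have rows >= 1, cols >= 1, bands >= 2")
  }
  if (length(object@wavelengths) != d[3]) {
    return(sprintf(
      "wavelength axis length (%d) does not match band count (%d)",
      length(object@wavelengths), d[3]
    ))
  }
  if (any(diff(object@wavelengths) <= 0)) {
    return("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(object@data))) {
    return("cube values must all be finite")
  }
  if (length(object@units) != 1L ||
      !object@units %in% c("raw", "reflectance_percent")) {
    return("units must be 'raw' or 'reflectance_percent'")
  }
  TRUE
})

#' Construct a HyperCube
#'
#' @param data rows x cols x bands numeric array.
#' @param wavelengths bands-length numeric vector (nm), strictly increasing.
#' @param units `"raw"` (digital numbers) or `"reflectance_percent"`.
#' @param name optional identifier.
#' @return A [HyperCube-class] object.
#' @export
#' @examples
#' cube <- HyperCube(array(runif(2 * 3 * 4), c(2, 3, 4)), seq(450, 900, length.out = 4))
#' cube
HyperCube <- function(data, wavelengths, units = "raw", name = "") {
  new("HyperCube",
    data = data, wavelengths = as.numeric(wavelengths),
    units = units, name = name
  )
}

#' @describeIn HyperCube Pixel array accessor.
#' @param x,object a `HyperCube`.
#' @export
cubeData <- function(x) x@data

#' @describeIn HyperCube Wavelength axis accessor (nm).
#' @export
wavelengths <- function(x) x@wavelengths

#' @describeIn HyperCube Units accessor.
#' @export
cubeUnits <- function(x) x@units

#' @describeIn HyperCube Dimensions `c(rows, cols, bands)`.
#' @export
cubeDim <- function(x) dim(x@data)

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "HyperCube '%s': %d x %d pixels, %d bands (%.2f-%.2f nm), units: %s\n",
    object@name, d[1], d[2], d[3],
    min(object@wavelengths), max(object@wavelengths), object@units
  ))
})

#' ReferenceFrames: white and dark calibration captures
#'
#' White (ideally ~99% reflective tile) and dark (shutter closed) reference
#' captures used for flat-field reflectance calibration. Either full frames
#' (rows x cols x bands) or single pushbroom line references
#' (1 x cols x bands) that are broadcast along the scan axis.
#'
#' @slot white raw-DN array, rows x cols x bands or 1 x cols x bands.
#' @slot dark array of the same shape as `white`.
#' @slot wavelengths wavelength axis shared with the raw cube (may be
#'   length 0 when unknown).
#'
#' @aliases ReferenceFrames-class
#' @export
setClass("ReferenceFrames",
  representation(white = "array", dark = "array", wavelengths = "numeric")
)

setValidity("ReferenceFrames", function(object) {
  dw <- dim(object@white)
  dd <- dim(object@dark)
  if (length(dw) != 3L || length(dd) != 3L) {
    return("white and dark references must be 3-D arrays")
  }
  if (!identical(dw, dd)) {
    return("white and dark references must have identical shape")
  }
  if (length(object@wavelengths) && length(object@wavelengths) != dw[3]) {
    return("wavelength axis does not match reference band count")
  }
  if (!all(is.finite(object@white)) || !all(is.finite(object@dark))) {
    return("reference values must be finite")
  }
  bad <- mean(object@white < object@dark)
  if (bad > 0.01) {
    return(sprintf(
      "white < dark on %.1f%% of samples (max 1%% tolerated)", 100 * bad
    ))
  }
  TRUE
})

#' Construct ReferenceFrames
#'
#' @param white,dark raw-DN arrays, rows x cols x bands (or 1 x cols x bands
#'   line references).
#' @param wavelengths optional shared wavelength axis (nm).
#' @return A [ReferenceFrames-class] object. White-below-dark samples are
#'   tolerated up to 1% (sensor noise) and reported by
#'   [validateReferences()].
#' @export
ReferenceFrames <- function(white, dark, wavelengths = numeric()) {
  new("ReferenceFrames",
    white = white, dark = dark,
    wavelengths = as.numeric(wavelengths)
  )
}

setMethod("show", "ReferenceFrames", function(object) {
  d <- dim(object@white)
  cat(sprintf(
    "ReferenceFrames: %d x %d x %d (%s)\n", d[1], d[2], d[3],
    if (d[1] == 1L) "pushbroom line, broadcast along rows" else "full frame"
  ))
})

#' GoldStandardMap: per-pixel class labels
#'
#' Integer label raster over a cube's spatial grid using the codes of
#' [classCodes()]: 0 unlabeled, 1 normal, 2 tumor, 3 vessel, 4 background.
#'
#' @slot labels integer matrix, rows x cols.
#' @slot provenance character vector of free-text records (reference pixel,
#'   threshold) appended by [assignClass()].
#'
#' @aliases GoldStandardMap-class
#' @export
setClass("GoldStandardMap",
  representation(labels = "matrix", provenance = "character"),
  prototype(provenance = character())
)

setValidity("GoldStandardMap", function(object) {
  if (!is.numeric(object@labels)) {
    return("labels must be an integer matrix")
  }
  if (!all(object@labels %in% 0:4)) {
    return("labels must use codes 0 (unlabeled) to 4 (background)")
  }
  TRUE
})

#' Construct a GoldStandardMap
#'
#' @param labels rows x cols integer matrix of class codes (defaults to all
#'   unlabeled when given a dimension vector via `dim`).
#' @param dim optional `c(rows, cols)` to create an empty (all-unlabeled) map.
#' @param provenance optional character records.
#' @return A [GoldStandardMap-class] object.
#' @export
GoldStandardMap <- function(labels = NULL, dim = NULL, provenance = character()) {
  if (is.null(labels)) {
    stopifnot(length(dim) == 2L)
    labels <- matrix(0L, dim[1], dim[2])
  }
  storage.mode(labels) <- "integer"
  new("GoldStandardMap", labels = labels, provenance = provenance)
}

#' @describeIn GoldStandardMap Label matrix accessor.
#' @param x,object a `GoldStandardMap`.
#' @export
labelMatrix <- function(x) x@labels

setMethod("show", "GoldStandardMap", function(object) {
  tab <- table(factor(object@labels, levels = 0:4,
                      labels = names(classCodes())))
  cat(sprintf("GoldStandardMap %d x %d\n", nrow(object@labels),
              ncol(object@labels)))
  print(tab)
})

#' TrainingDataset: labeled spectral signatures
#'
#' One row per labeled pixel: pre-processed spectrum, class code, subject
#' (patient) identifier for grouped cross-validation, and an optional tumor
#' subtype annotation.
#'
#' @slot spectra N x bands numeric matrix.
#' @slot labels integer N-vector of class codes 1..4.
#' @slot groups character N-vector of subject identifiers.
#' @slot subtype character N-vector (`""` where not annotated).
#'
#' @aliases TrainingDataset-class
#' @export
setClass("TrainingDataset",
  representation(
    spectra = "matrix", labels = "integer",
    groups = "character", subtype = "character"
  )
)

setValidity("TrainingDataset", function(object) {
  n <- nrow(object@spectra)
  if (length(object@labels) != n || length(object@groups) != n) {
    return("spectra, labels and groups must agree in length")
  }
  if (length(object@subtype) && length(object@subtype) != n) {
    return("subtype annotation must have one entry per row")
  }
  if (!all(object@labels %in% 1:4)) {
    return("labels must be class codes 1..4")
  }
  if (!all(is.finite(object@spectra))) {
    return("spectra must be finite")
  }
  TRUE
})

#' Construct a TrainingDataset
#'
#' @param spectra N x bands matrix of (pre-processed) spectra.
#' @param labels integer class codes 1..4.
#' @param groups subject identifiers (recycled if length 1).
#' @param subtype optional per-row tumor subtype annotation.
#' @return A [TrainingDataset-class] object.
#' @export
TrainingDataset <- function(spectra, labels, groups = "s1",
                            subtype = character()) {
  spectra <- as.matrix(spectra)
  if (length(groups) == 1L) groups <- rep(groups, nrow(spectra))
  new("TrainingDataset",
    spectra = spectra, labels = as.integer(labels),
    groups = as.character(groups), subtype = as.character(subtype)
  )
}

#' @describeIn TrainingDataset Number of signatures.
#' @param x,object a `TrainingDataset`.
#' @export
nSignatures <- function(x) nrow(x@spectra)

#' @describeIn TrainingDataset Per-class signature counts (named by class).
#' @export
classCounts <- function(x) {
  tab <- table(factor(x@labels, levels = 1:4,
                      labels = names(.tissueCodes())))
  setNames(as.integer(tab), names(tab))
}

setMethod("show", "TrainingDataset", function(object) {
  cat(sprintf(
    "TrainingDataset: %d signatures x %d bands, %d subject(s)\n",
    nrow(object@spectra), ncol(object@spectra),
    length(unique(object@groups))
  ))
  print(classCounts(object))
})

#' ProbabilityMap: per-pixel class probabilities
#'
#' rows x cols x nclass array of per-pixel class probabilities produced by
#' the supervised stage; each pixel's vector is non-negative and sums to 1
#' (tolerance 1e-6).
#'
#' @slot probs numeric array, rows x cols x nclass.
#' @slot classOrder integer class codes giving the meaning of the third
#'   axis, in order.
#'
#' @aliases ProbabilityMap-class
#' @export
setClass("ProbabilityMap",
  representation(probs = "array", classOrder = "integer")
)

setValidity("ProbabilityMap", function(object) {
  d <- dim(object@probs)
  if (length(d) != 3L) {
    return("probs must be rows x cols x nclass")
  }
  if (length(object@classOrder) != d[3]) {
    return("classOrder length must match the class axis")
  }
  if (any(object@probs < -1e-12)) {
    return("probabilities must be non-negative")
  }
  s <- apply(object@probs, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-6)) {
    return("per-pixel probabilities must sum to 1 (tol 1e-6)")
  }
  TRUE
})

#' Construct a ProbabilityMap
#'
#' @param probs rows x cols x nclass array.
#' @param classOrder integer class codes for the third axis.
#' @return A [ProbabilityMap-class] object.
#' @export
ProbabilityMap <- function(probs, classOrder = as.integer(.tissueCodes())) {
  new("ProbabilityMap", probs = probs, classOrder = as.integer(classOrder))
}

#' @describeIn ProbabilityMap Probability array accessor.
#' @param x,object a `ProbabilityMap`.
#' @export
probArray <- function(x) x@probs

#' @describeIn ProbabilityMap Class codes of the probability axis.
#' @export
classOrder <- function(x) x@classOrder

#' @describeIn ProbabilityMap Per-pixel most-probable class codes
#'   (ties broken toward the lowest class code).
#' @export
argmaxMap <- function(x) {
  d <- dim(x@probs)
  m <- matrix(x@probs, d[1] * d[2], d[3])
  idx <- max.col(m, ties.method = "first")
  matrix(x@classOrder[idx], d[1], d[2])
}

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@probs)
  cat(sprintf(
    "ProbabilityMap: %d x %d pixels, %d classes (codes %s)\n",
    d[1], d[2], d[3], paste(object@classOrder, collapse = ", ")
  ))
})

#' SegmentationMap: unsupervised cluster assignment
#'
#' rows x cols integer raster of cluster ids 1..K; every id occurs at least
#' once.
#'
#' @slot clusterId integer matrix, rows x cols.
#' @slot K number of clusters.
#'
#' @aliases SegmentationMap-class
#' @export
setClass("SegmentationMap",
  representation(clusterId = "matrix", K = "integer")
)

setValidity("SegmentationMap", function(object) {
  ids <- object@clusterId
  K <- object@K
  if (length(K) != 1L || K < 1L) return("K must be a positive integer")
  if (!all(ids %in% seq_len(K))) return("cluster ids must lie in 1..K")
  if (!all(seq_len(K) %in% ids)) return("every cluster 1..K must be non-empty")
  TRUE
})

#' Construct a SegmentationMap
#'
#' @param clusterId rows x cols integer matrix of cluster ids 1..K.
#' @param K number of clusters.
#' @return A [SegmentationMap-class] object.
#' @export
SegmentationMap <- function(clusterId, K = max(clusterId)) {
  storage.mode(clusterId) <- "integer"
  new("SegmentationMap", clusterId = clusterId, K = as.integer(K))
}

#' @describeIn SegmentationMap Cluster-id matrix accessor.
#' @param x,object a `SegmentationMap`.
#' @export
clusterIds <- function(x) x@clusterId

#' @describeIn SegmentationMap Number of clusters.
#' @export
nClusters <- function(x) x@K

setMethod("show", "SegmentationMap", function(object) {
  cat(sprintf(
    "SegmentationMap: %d x %d pixels, K = %d\n",
    nrow(object@clusterId), ncol(object@clusterId), object@K
  ))
})

#' ClusterDensities: per-cluster class densities
#'
#' For each cluster, the fraction of its pixels whose (filtered) supervised
#' class is each of the tissue classes; each row is non-negative and sums
#' to 1.
#'
#' @slot densities K x nclass numeric matrix.
#' @slot classOrder integer class codes for the columns.
#'
#' @aliases ClusterDensities-class
#' @export
setClass("ClusterDensities",
  representation(densities = "matrix", classOrder = "integer")
)

setValidity("ClusterDensities", function(object) {
  if (ncol(object@densities) != length(object@classOrder)) {
    return("classOrder length must match density columns")
  }
  if (any(object@densities < 0)) return("densities must be non-negative")
  if (any(abs(rowSums(object@densities) - 1) > 1e-9)) {
    return("each cluster's densities must sum to 1")
  }
  TRUE
})

#' @describeIn ClusterDensities-class Density matrix accessor (K x nclass).
#' @param x a `ClusterDensities`.
#' @export
densityMatrix <- function(x) x@densities

setMethod("show", "ClusterDensities", function(object) {
  cat(sprintf(
    "ClusterDensities: %d clusters x %d classes\n",
    nrow(object@densities), ncol(object@densities)
  ))
})

#' TMDMap: three-maximum-density delineation map
#'
#' RGB rendering of the fused supervised/unsupervised result: within each
#' cluster the three largest class densities are renormalized and blended
#' in class colors (tumor red, normal green, vessel blue, background
#' black or white), so each cluster is filled with one convex combination
#' of class colors.
#'
#' @slot rgb rows x cols x 3 array in `[0, 1]`.
#' @slot colors class-color matrix used for the rendering.
#'
#' @aliases TMDMap-class
#' @export
setClass("TMDMap", representation(rgb = "array", colors = "matrix"))

setValidity("TMDMap", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L) return("rgb must be rows x cols x 3")
  if (any(object@rgb < 0) || any(object@rgb > 1)) {
    return("rgb values must lie in [0, 1]")
  }
  TRUE
})

#' @describeIn TMDMap-class RGB array accessor.
#' @param x a `TMDMap`.
#' @export
tmdRgb <- function(x) x@rgb

setMethod("show", "TMDMap", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("TMDMap: %d x %d pixels\n", d[1], d[2]))
})
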