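## Spectral-angle-mapper (SAM) assisted gold-standard labeling and
## training-dataset assembly.
##
## The labeling workflow mirrors how surgeons build gold-standard maps:
## pick a trusted reference pixel (e.g. over a biopsy-confirmed marker),
## highlight all pixels whose spectral angle to it falls below a threshold,
## and assign the highlighted set to one of the four classes. Only small,
## reliable pixel sets are expected; boundary pixels stay unlabeled.

#' Spectral angle between two spectra
#'
#' The angle between two spectra viewed as vectors,
#' `acos(<x, y> / (|x| |y|))`, evaluated through the chord length of the
#' unit-normalized vectors (`2 asin(|u - v| / 2)`), which is exact for
#' identical or proportional spectra where the plain arc-cosine loses
#' precision. SAM is invariant to positive scaling of either argument,
#' which makes it robust to illumination intensity differences.
#'
#' @param x,y numeric spectra of equal length, neither all-zero.
#' @return Angle in radians, in `[0, pi]`.
#' @export
#' @examples
#' samAngle(c(1, 0), c(0, 1))  # pi/2
#' samAngle(1:5, 2 * (1:5))    # 0
samAngle <- function(x, y) {
  if (length(x) != length(y)) stop("spectra must have equal length")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("SAM is undefined for a zero spectrum")
  d <- sqrt(sum((x / nx - y / ny)^2))
  2 * asin(min(1, d / 2))
}

# angles of every pixel spectrum to a reference spectrum; zero-norm pixels
# get Inf (never similar to anything)
.samAngleField <- function(mat, ref) {
  nref <- sqrt(sum(ref^2))
  norms <- sqrt(rowSums(mat^2))
  cosv <- as.vector(mat %*% ref) / (norms * nref)
  ang <- acos(pmin(1, pmax(-1, cosv)))
  ang[norms == 0] <- Inf
  ang
}

#' Select pixels spectrally similar to a reference pixel
#'
#' Marks every pixel whose spectral angle to the reference pixel's spectrum
#' is at most `threshold`. The reference pixel itself is always selected;
#' all-zero pixels never are.
#'
#' @param cube a [HyperCube-class].
#' @param ref integer `c(row, col)` of the reference pixel.
#' @param threshold maximum spectral angle, radians (> 0).
#' @return rows x cols logical mask.
#' @export
samSelect <- function(cube, ref, threshold) {
  d <- dim(cube@data)
  if (length(ref) != 2L || ref[1] < 1 || ref[1] > d[1] ||
      ref[2] < 1 || ref[2] > d[2]) {
    stop("reference pixel outside the cube")
  }
  if (threshold <= 0) stop("threshold must be positive")
  refspec <- as.numeric(cube@data[ref[1], ref[2], ])
  if (all(refspec == 0)) stop("reference pixel has an all-zero spectrum")
  ang <- .samAngleField(.pixelMatrix(cube), refspec)
  mask <- matrix(ang <= threshold, d[1], d[2])
  mask[ref[1], ref[2]] <- TRUE
  mask
}

#' Assign a class to masked pixels of a gold-standard map
#'
#' @param map a [GoldStandardMap-class].
#' @param mask rows x cols logical selection.
#' @param class_code class code 1..4 (see [classCodes()]).
#' @param overwrite allow relabeling pixels that already carry a different
#'   non-zero label; without it such an overlap is an error (a safety rule:
#'   silent relabeling of surgeon-confirmed pixels is never wanted).
#' @param note optional provenance record (reference pixel, threshold).
#' @return The updated [GoldStandardMap-class].
#' @export
assignClass <- function(map, mask, class_code, overwrite = FALSE, note = NULL) {
  stopifnot(is(map, "GoldStandardMap"))
  if (!class_code %in% 1:4) stop("class_code must be 1..4")
  if (!identical(dim(mask), dim(map@labels))) {
    stop("mask shape does not match the label map")
  }
  clash <- mask & map@labels != 0L & map@labels != as.integer(class_code)
  if (any(clash) && !overwrite) {
    stop(sum(clash), " selected pixel(s) already labeled with another ",
         "class; use overwrite = TRUE to relabel")
  }
  labels <- map@labels
  labels[mask] <- as.integer(class_code)
  prov <- map@provenance
  if (!is.null(note)) prov <- c(prov, note)
  GoldStandardMap(labels = labels, provenance = prov)
}

#' Assemble a training dataset from labeled cubes
#'
#' Extracts one row per labeled pixel from each (cube, gold-standard map)
#' pair; `groups` carries the subject identifier so grouped
#' cross-validation can respect patient boundaries. Unlabeled pixels never
#' contribute rows.
#'
#' @param pairs list of `list(cube =, map =, subject =)` entries (an
#'   optional `subtype` string annotates all tumor rows of the capture).
#' @return A [TrainingDataset-class].
#' @export
assembleDataset <- function(pairs) {
  spectra <- list()
  labels <- list()
  groups <- list()
  subtype <- list()
  for (p in pairs) {
    cube <- p$cube
    map <- p$map
    stopifnot(is(cube, "HyperCube"), is(map, "GoldStandardMap"))
    if (!identical(dim(map@labels), dim(cube@data)[1:2])) {
      stop("label map does not match its cube's spatial grid")
    }
    sel <- which(map@labels != 0L)
    if (!length(sel)) next
    mat <- .pixelMatrix(cube)
    spectra[[length(spectra) + 1L]] <- mat[sel, , drop = FALSE]
    lab <- map@labels[sel]
    labels[[length(labels) + 1L]] <- lab
    groups[[length(groups) + 1L]] <- rep(as.character(p$subject), length(sel))
    st <- rep("", length(sel))
    if (!is.null(p$subtype)) st[lab == classCodes()[["tumor"]]] <- p$subtype
    subtype[[length(subtype) + 1L]] <- st
  }
  if (!length(spectra)) stop("no labeled pixels in any capture")
  TrainingDataset(
    spectra = do.call(rbind, spectra),
    labels = unlist(labels),
    groups = unlist(groups),
    subtype = unlist(subtype)
  )
}

#' Summarize a training dataset
#'
#' Per-class signature counts, broken down by tumor subtype where the
#' dataset carries subtype annotations, plus the grand total (which always
#' equals the number of rows).
#'
#' @param ds a [TrainingDataset-class].
#' @return A data frame with columns `class`, `subtype`, `pixels`, ending
#'   in a `total` row.
#' @export
#' @examples
#' ds <- TrainingDataset(matrix(rnorm(12), 6), labels = c(1, 1, 2, 3, 4, 4))
#' datasetSummary(ds)
datasetSummary <- function(ds) {
  stopifnot(is(ds, "TrainingDataset"))
  rows <- list()
  codes <- .tissueCodes()
  has_subtype <- length(ds@subtype) > 0 && any(nzchar(ds@subtype))
  for (cl in names(codes)) {
    idx <- ds@labels == codes[[cl]]
    if (!any(idx)) next
    if (cl == "tumor" && has_subtype) {
      st <- ds@subtype[idx]
      st[!nzchar(st)] <- "(unspecified)"
      for (s in unique(st)) {
        rows[[length(rows) + 1L]] <-
          data.frame(class = cl, subtype = s, pixels = sum(st == s))
      }
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, subtype = "", pixels = sum(idx))
    }
  }
  rows[[length(rows) + 1L]] <-
    data.frame(class = "total", subtype = "", pixels = nSignatures(ds))
  do.call(rbind, rows)
}
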