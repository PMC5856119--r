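## Spectral homogenization chain: clip -> smooth -> downsample -> normalize.
##
## The chain makes spectral signatures comparable across pixels and
## acquisitions before the supervised and unsupervised stages: the noisy
## sensor extremes are clipped away, spectra are denoised along the band
## axis, dimensionality is reduced by contiguous band averaging, and each
## pixel's spectrum is scaled to a common range.

#' PreprocessConfig: parameters of the homogenization chain
#'
#' @slot keepRange wavelength window `c(low, high)` in nm retained by the
#'   band clip.
#' @slot smoothWindow odd filter length (bands); 1 disables smoothing.
#' @slot smoothKind `"moving_average"` or `"savitzky_golay"`.
#' @slot targetBands band count after contiguous averaging (`NA` disables).
#' @slot normalize `"none"`, `"unit_max"`, `"unit_area"` or `"standardize"`.
#'
#' @aliases PreprocessConfig-class
#' @export
setClass("PreprocessConfig",
  representation(
    keepRange = "numeric", smoothWindow = "integer",
    smoothKind = "character", targetBands = "integer",
    normalize = "character"
  )
)

setValidity("PreprocessConfig", function(object) {
  if (length(object@keepRange) != 2L ||
      object@keepRange[1] >= object@keepRange[2]) {
    return("keepRange must be c(low, high) with low < high")
  }
  if (object@smoothWindow < 1L || object@smoothWindow %% 2L == 0L) {
    return("smoothWindow must be an odd integer >= 1")
  }
  if (!object@smoothKind %in% c("moving_average", "savitzky_golay")) {
    return("smoothKind must be 'moving_average' or 'savitzky_golay'")
  }
  if (!object@normalize %in% c("none", "unit_max", "unit_area", "standardize")) {
    return("unknown normalize mode")
  }
  TRUE
})

#' Construct a PreprocessConfig
#'
#' Defaults: keep 450-900 nm (discards the noisy sensor extremes of a
#' 400-1000 nm VNIR axis), 5-band moving-average smoothing, reduction to
#' 128 bands, unit-max normalization.
#'
#' @param keep_range wavelength window, nm.
#' @param smooth_window odd integer >= 1.
#' @param smooth_kind `"moving_average"` or `"savitzky_golay"`.
#' @param target_bands integer or `NA` to skip band averaging.
#' @param normalize normalization mode.
#' @return A [PreprocessConfig-class].
#' @export
#' @examples
#' preprocessConfig()
#' preprocessConfig(smooth_window = 1, target_bands = NA, normalize = "none")
preprocessConfig <- function(keep_range = c(450, 900), smooth_window = 5L,
                             smooth_kind = "moving_average",
                             target_bands = 128L, normalize = "unit_max") {
  new("PreprocessConfig",
    keepRange = as.numeric(keep_range),
    smoothWindow = as.integer(smooth_window),
    smoothKind = smooth_kind,
    targetBands = as.integer(target_bands),
    normalize = normalize
  )
}

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(
    "PreprocessConfig: clip [%g, %g] nm | smooth %s(%d) | %s bands | normalize %s\n",
    object@keepRange[1], object@keepRange[2], object@smoothKind,
    object@smoothWindow,
    if (is.na(object@targetBands)) "keep" else object@targetBands,
    object@normalize
  ))
})

# cube -> pixel matrix (n_px x bands), pixels in column-major grid order
.pixelMatrix <- function(cube) {
  d <- dim(cube@data)
  matrix(cube@data, d[1] * d[2], d[3])
}

.matrixToCube <- function(mat, template, wavelengths = template@wavelengths) {
  d <- dim(template@data)
  HyperCube(array(mat, c(d[1], d[2], ncol(mat))), wavelengths,
            units = template@units, name = template@name)
}

#' Clip a cube to a wavelength window
#'
#' @param cube a [HyperCube-class].
#' @param low_nm,high_nm retained wavelength window (inclusive).
#' @return A [HyperCube-class] with only bands in `[low_nm, high_nm]`.
#' @export
clipBands <- function(cube, low_nm, high_nm) {
  keep <- which(cube@wavelengths >= low_nm & cube@wavelengths <= high_nm)
  if (length(keep) < 2L) {
    stop(sprintf(
      "clipping to [%g, %g] nm retains %d band(s); at least 2 required",
      low_nm, high_nm, length(keep)
    ))
  }
  if (length(keep) == length(cube@wavelengths)) return(cube)
  .matrixToCube(.pixelMatrix(cube)[, keep, drop = FALSE], cube,
                cube@wavelengths[keep])
}

# smoothing kernel: uniform for moving average, central Savitzky-Golay row
# (poly order min(3, window - 2)) otherwise
.smoothKernel <- function(window, kind) {
  if (kind == "moving_average") {
    rep(1 / window, window)
  } else {
    p <- min(3L, window - 2L)
    sg <- signal::sgolay(p = p, n = window)
    as.numeric(sg[(window + 1L) / 2L, ])
  }
}

#' Smooth spectra along the band axis
#'
#' Filters each pixel's spectrum with a length-`window` kernel (uniform
#' moving average or central Savitzky-Golay coefficients), replicating the
#' first and last band values past the edges. `window = 1` is the identity.
#'
#' @param cube a [HyperCube-class].
#' @param window odd integer >= 1, at most the band count.
#' @param kind `"moving_average"` or `"savitzky_golay"`.
#' @return The smoothed [HyperCube-class].
#' @export
smoothSpectra <- function(cube, window,
                          kind = c("moving_average", "savitzky_golay")) {
  kind <- match.arg(kind)
  window <- as.integer(window)
  bands <- dim(cube@data)[3]
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  if (window > bands) stop("smoothing window exceeds band count")
  if (window == 1L) return(cube)
  kern <- .smoothKernel(window, kind)
  r <- (window - 1L) %/% 2L
  mat <- .pixelMatrix(cube)
  pad <- cbind(
    mat[, rep(1L, r), drop = FALSE], mat,
    mat[, rep(bands, r), drop = FALSE]
  )
  out <- matrix(0, nrow(mat), bands)
  for (j in seq_len(window)) {
    out <- out + kern[j] * pad[, j:(j + bands - 1L), drop = FALSE]
  }
  .matrixToCube(out, cube)
}

#' Reduce the band count by contiguous averaging
#'
#' Splits the band axis into `target_bands` contiguous groups of (near-)
#' equal size and replaces each group by its mean value and mean
#' wavelength.
#'
#' @param cube a [HyperCube-class].
#' @param target_bands integer in `[1, bands]` (equal to `bands` is the
#'   identity).
#' @return The band-averaged [HyperCube-class].
#' @export
downsampleBands <- function(cube, target_bands) {
  bands <- dim(cube@data)[3]
  target_bands <- as.integer(target_bands)
  if (target_bands < 1L || target_bands > bands) {
    stop("target_bands must lie in [1, bands]")
  }
  if (target_bands == bands) return(cube)
  edges <- floor(seq(0, bands, length.out = target_bands + 1L))
  grp <- rep(seq_len(target_bands), times = diff(edges))
  mat <- .pixelMatrix(cube)
  out <- t(rowsum(t(mat), grp) / as.vector(table(grp)))
  wl <- as.numeric(tapply(cube@wavelengths, grp, mean))
  .matrixToCube(out, cube, wl)
}

#' Normalize spectra pixel-wise
#'
#' Modes: `unit_max` scales each spectrum so its maximum is 1; `unit_area`
#' so it sums to 1; `standardize` to per-pixel mean 0 / sd 1; `none` is the
#' identity. Degenerate spectra (all-zero for the first two modes, constant
#' for `standardize`) are left untouched and counted in the attached
#' `"degenerate"` attribute (a rows x cols logical matrix); a warning
#' reports their number.
#'
#' @param cube a [HyperCube-class].
#' @param mode normalization mode.
#' @return The normalized [HyperCube-class] with attribute `"degenerate"`.
#' @export
normalizeSpectra <- function(cube, mode = c("unit_max", "unit_area",
                                            "standardize", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(cube)
  mat <- .pixelMatrix(cube)
  d <- dim(cube@data)
  if (mode %in% c("unit_max", "unit_area") && any(mat < 0)) {
    stop("unit_max/unit_area normalization requires non-negative spectra")
  }
  degen <- switch(mode,
    unit_max = ,
    unit_area = rowSums(mat) == 0,
    standardize = apply(mat, 1, function(r) all(r == r[1]))
  )
  ok <- !degen
  out <- mat
  if (mode == "unit_max") {
    out[ok, ] <- mat[ok, , drop = FALSE] /
      apply(mat[ok, , drop = FALSE], 1, max)
  } else if (mode == "unit_area") {
    out[ok, ] <- mat[ok, , drop = FALSE] / rowSums(mat[ok, , drop = FALSE])
  } else {
    mu <- rowMeans(mat[ok, , drop = FALSE])
    sdv <- apply(mat[ok, , drop = FALSE], 1, sd)
    out[ok, ] <- (mat[ok, , drop = FALSE] - mu) / sdv
  }
  res <- .matrixToCube(out, cube)
  if (any(degen)) {
    warning(sum(degen), " degenerate spectra left unnormalized")
  }
  attr(res, "degenerate") <- matrix(degen, d[1], d[2])
  res
}

#' Run the full homogenization chain
#'
#' Applies, in fixed order: band clip, spectral smoothing, contiguous band
#' averaging and per-pixel normalization, as configured by a
#' [PreprocessConfig-class]. The executed stages are recorded in the
#' `"stageLog"` attribute of the result.
#'
#' @param cube a [HyperCube-class] (typically calibrated reflectance).
#' @param config a [PreprocessConfig-class].
#' @return The pre-processed [HyperCube-class] with a `"stageLog"`
#'   attribute (data frame of stage names and wall-clock seconds).
#' @export
preprocess <- function(cube, config = preprocessConfig()) {
  stopifnot(is(cube, "HyperCube"), is(config, "PreprocessConfig"))
  validObject(config)
  stages <- character()
  secs <- numeric()
  step <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    stages <<- c(stages, name)
    secs <<- c(secs, proc.time()[["elapsed"]] - t0)
    val
  }
  out <- step("clip", clipBands(cube, config@keepRange[1], config@keepRange[2]))
  if (config@smoothWindow > 1L) {
    out <- step("smooth", smoothSpectra(out, config@smoothWindow,
                                        config@smoothKind))
  }
  if (!is.na(config@targetBands) &&
      config@targetBands < dim(out@data)[3]) {
    out <- step("downsample", downsampleBands(out, config@targetBands))
  }
  if (config@normalize != "none") {
    out <- step("normalize", suppressWarnings(
      normalizeSpectra(out, config@normalize)
    ))
  }
  attr(out, "stageLog") <- data.frame(stage = stages, seconds = secs)
  out
}
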