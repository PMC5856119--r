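## Flat-field reflectance calibration from white/dark reference captures.

# Broadcast a 1 x cols x bands line reference along the scan (row) axis.
.broadcastRef <- function(ref, rows) {
  d <- dim(ref)
  if (d[1] == rows) return(ref)
  if (d[1] != 1L) {
    stop("reference has ", d[1], " rows; expected 1 (line) or ", rows)
  }
  out <- array(0, c(rows, d[2], d[3]))
  out[] <- rep(ref, each = rows)  # ref is 1 x cols x bands; row axis fastest
  out
}

#' Calibrate a raw cube to percent reflectance
#'
#' Converts raw digital numbers to percent reflectance using white and dark
#' reference captures taken under the acquisition's illumination:
#' `beta = 100 * (alpha - delta) / (gamma - delta)`, where `alpha` is the
#' raw cube and `gamma`, `delta` the white and dark references. A pushbroom
#' line reference (1 x cols x bands) is broadcast along the scan axis.
#'
#' Samples where the denominator `gamma - delta` is not positive are set to
#' 0 and the affected pixels flagged. Negative reflectance (sensor noise
#' driving `alpha` below `delta`) is clipped to 0; values above 100%
#' (specular highlights) are kept and flagged separately, since bright
#' pixels must remain classifiable as background.
#'
#' @param raw a [HyperCube-class] with `units == "raw"`.
#' @param refs a [ReferenceFrames-class] with the same band count.
#' @return A list:
#' \describe{
#'   \item{cube}{calibrated [HyperCube-class], `units = "reflectance_percent"`.}
#'   \item{flagged}{rows x cols logical: pixels with any dead reference
#'     sample (`gamma <= delta`).}
#'   \item{specular}{rows x cols logical: pixels with any band above 100%.}
#' }
#' @export
calibrate <- function(raw, refs) {
  stopifnot(is(raw, "HyperCube"), is(refs, "ReferenceFrames"))
  if (raw@units != "raw") {
    stop("cube is already calibrated (units = ", raw@units, ")")
  }
  d <- dim(raw@data)
  dr <- dim(refs@white)
  if (dr[3] != d[3]) {
    stop(sprintf("band-count mismatch: cube has %d bands, references %d",
                 d[3], dr[3]))
  }
  if (dr[2] != d[2]) {
    stop(sprintf("column mismatch: cube has %d cols, references %d",
                 d[2], dr[2]))
  }
  white <- .broadcastRef(refs@white, d[1])
  dark <- .broadcastRef(refs@dark, d[1])
  denom <- white - dark
  if (all(denom <= 0)) {
    stop("references unusable: white - dark is nowhere positive")
  }
  dead <- denom <= 0
  beta <- array(0, d)
  beta[!dead] <- 100 * (raw@data[!dead] - dark[!dead]) / denom[!dead]
  beta[beta < 0] <- 0
  flagged <- apply(dead, c(1, 2), any)
  specular <- apply(beta > 100, c(1, 2), any)
  cube <- HyperCube(beta, raw@wavelengths,
                    units = "reflectance_percent", name = raw@name)
  list(cube = cube, flagged = flagged, specular = specular)
}

#' Sanity-check white/dark reference captures
#'
#' Reports the fraction of samples where the white reference does not
#' exceed the dark reference, the per-band mean white spectrum (dark
#' subtracted), and the bands whose mean dynamic range falls below a floor
#' (such bands carry essentially no calibration signal).
#'
#' @param refs a [ReferenceFrames-class].
#' @param floor minimum acceptable per-band mean of `white - dark`
#'   (raw DN; default 1).
#' @return A list with `fraction_invalid`, `mean_white` (per-band mean of
#'   `white - dark`) and `low_bands` (indices below the floor).
#' @export
validateReferences <- function(refs, floor = 1) {
  stopifnot(is(refs, "ReferenceFrames"))
  denom <- refs@white - refs@dark
  mean_white <- apply(denom, 3, mean)
  list(
    fraction_invalid = mean(denom <= 0),
    mean_white = mean_white,
    low_bands = which(mean_white < floor)
  )
}
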