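#' Tissue class codes
#'
#' The four-class scheme used throughout the package, plus code 0 for
#' unlabeled pixels: normal tissue, tumor tissue, blood
#' vessel/hypervascularized tissue and background (non-tissue material in
#' the surgical scene).
#'
#' @return Named integer vector `c(unlabeled = 0, normal = 1, tumor = 2,
#'   vessel = 3, background = 4)`.
#' @export
#' @examples
#' classCodes()
classCodes <- function() {
  c(unlabeled = 0L, normal = 1L, tumor = 2L, vessel = 3L, background = 4L)
}

#' Display colors for the tissue classes
#'
#' Convention used by the delineation maps: normal tissue green, tumor red,
#' blood vessel/hypervascularized tissue blue, background black (optionally
#' white).
#'
#' @param background `"black"` (default) or `"white"`.
#' @return 4 x 3 numeric matrix of RGB values in `[0, 1]`, rownames
#'   `normal`, `tumor`, `vessel`, `background`.
#' @export
#' @examples
#' classColors()
classColors <- function(background = c("black", "white")) {
  background <- match.arg(background)
  bg <- if (background == "black") c(0, 0, 0) else c(1, 1, 1)
  m <- rbind(
    normal     = c(0, 1, 0),
    tumor      = c(1, 0, 0),
    vessel     = c(0, 0, 1),
    background = bg
  )
  colnames(m) <- c("r", "g", "b")
  m
}

# class codes 1..4 in label order (no unlabeled)
.tissueCodes <- function() classCodes()[c("normal", "tumor", "vessel", "background")]

# tie-break priority for majority voting: clinically conservative
.votePriority <- function() classCodes()[c("tumor", "vessel", "normal", "background")]
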