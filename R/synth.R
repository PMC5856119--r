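## Synthetic intraoperative phantom scenes: raw pushbroom cube + white/dark
## line references + ground-truth label map, with the statistical structure
## the pipeline assumes (class-distinct smooth signatures, intra-/inter-
## subject variability, sensor noise, illumination gain, specular bright
## pixels). Synthesis happens in the raw digital-number domain by inverting
## the reflectance calibration, so the calibration module is exercised too.

#' PhantomSpec: parameters of the synthetic scene generator
#'
#' Defaults describe a 128 x 128 pixel, 300-band 400-1000 nm scene on a
#' 12-bit sensor scale (white level ~3500 DN, dark ~100 DN, saturation
#' 4095 DN) whose four classes are laid out as a background ring, normal
#' parenchyma, sinuous vessel curves and one tumor blob.
#'
#' @slot rows,cols,bands scene dimensions.
#' @slot wlRange wavelength range, nm.
#' @slot nGauss random Gaussian components per class endmember.
#' @slot minSeparation minimum pairwise spectral angle between class
#'   endmembers, radians.
#' @slot jitterSd intra-subject per-pixel amplitude jitter sd (relative).
#' @slot subjectSd inter-subject smooth spectral offset sd (relative).
#' @slot noiseSd additive sensor noise sd on raw DN.
#' @slot refNoiseSd capture noise sd of the reference lines, DN.
#' @slot whiteLevel,darkLevel,saturationDn raw DN scale.
#' @slot gainAmplitude smooth multiplicative illumination gain amplitude
#'   along the line axis.
#' @slot specularFraction fraction of pixels saturated by specular
#'   reflections.
#' @slot deadPixelFraction fraction of reference samples with white = dark.
#' @slot tumorPresent whether the scene contains a tumor blob.
#' @slot tumorRadiusFrac tumor radius as a fraction of `min(rows, cols)`.
#' @slot ringFrac background ring width as a fraction of `min(rows, cols)`.
#' @slot nVessels,vesselWidth vessel curve count and half-width (px).
#' @slot boundaryMargin erosion margin (px): pixels this close to another
#'   region stay unlabeled in the truth map.
#'
#' @aliases PhantomSpec-class
#' @export
setClass("PhantomSpec",
  representation(
    rows = "integer", cols = "integer", bands = "integer",
    wlRange = "numeric", nGauss = "integer", minSeparation = "numeric",
    jitterSd = "numeric", subjectSd = "numeric", noiseSd = "numeric",
    refNoiseSd = "numeric", whiteLevel = "numeric", darkLevel = "numeric",
    saturationDn = "numeric", gainAmplitude = "numeric",
    specularFraction = "numeric", deadPixelFraction = "numeric",
    tumorPresent = "logical", tumorRadiusFrac = "numeric",
    ringFrac = "numeric", nVessels = "integer", vesselWidth = "numeric",
    boundaryMargin = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (object@rows < 8L || object@cols < 8L || object@bands < 4L) {
    return("phantom must be at least 8 x 8 pixels with >= 4 bands")
  }
  sds <- c(object@jitterSd, object@subjectSd, object@noiseSd,
           object@refNoiseSd)
  if (any(sds < 0)) return("all noise standard deviations must be >= 0")
  fr <- c(object@specularFraction, object@deadPixelFraction,
          object@tumorRadiusFrac, object@ringFrac)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@whiteLevel <= object@darkLevel) {
    return("whiteLevel must exceed darkLevel")
  }
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param rows,cols,bands scene dimensions (default 128 x 128 x 300).
#' @param wl_range wavelength range nm (default 400-1000).
#' @param n_gauss Gaussian components per endmember (default 4).
#' @param min_separation minimum pairwise endmember spectral angle,
#'   radians (default 0.15).
#' @param jitter_sd intra-subject amplitude jitter sd (default 0.02).
#' @param subject_sd inter-subject spectral offset sd (default 0.04).
#' @param noise_sd raw-DN sensor noise sd (default 20).
#' @param ref_noise_sd reference capture noise sd (default 2).
#' @param white_level,dark_level,saturation_dn DN scale (3500/100/4095).
#' @param gain_amplitude illumination gain amplitude (default 0.1).
#' @param specular_fraction saturated-pixel fraction (default 0.002).
#' @param dead_pixel_fraction white-equals-dark reference sample fraction
#'   (default 0).
#' @param tumor_present include a tumor blob (default `TRUE`).
#' @param tumor_radius_frac tumor radius / min dimension (default 0.16).
#' @param ring_frac background ring width / min dimension (default 0.08).
#' @param n_vessels,vessel_width vessel count and half-width (2 and 3).
#' @param boundary_margin unlabeled erosion margin in px (default 2).
#' @return A [PhantomSpec-class].
#' @export
#' @examples
#' phantomSpec(rows = 32, cols = 32, bands = 40)
phantomSpec <- function(rows = 128L, cols = 128L, bands = 300L,
                        wl_range = c(400, 1000), n_gauss = 4L,
                        min_separation = 0.15, jitter_sd = 0.02,
                        subject_sd = 0.04, noise_sd = 20,
                        ref_noise_sd = 2, white_level = 3500,
                        dark_level = 100, saturation_dn = 4095,
                        gain_amplitude = 0.1, specular_fraction = 0.002,
                        dead_pixel_fraction = 0, tumor_present = TRUE,
                        tumor_radius_frac = 0.16, ring_frac = 0.08,
                        n_vessels = 2L, vessel_width = 3,
                        boundary_margin = 2L) {
  new("PhantomSpec",
    rows = as.integer(rows), cols = as.integer(cols),
    bands = as.integer(bands), wlRange = as.numeric(wl_range),
    nGauss = as.integer(n_gauss), minSeparation = min_separation,
    jitterSd = jitter_sd, subjectSd = subject_sd, noiseSd = noise_sd,
    refNoiseSd = ref_noise_sd, whiteLevel = white_level,
    darkLevel = dark_level, saturationDn = saturation_dn,
    gainAmplitude = gain_amplitude, specularFraction = specular_fraction,
    deadPixelFraction = dead_pixel_fraction, tumorPresent = tumor_present,
    tumorRadiusFrac = tumor_radius_frac, ringFrac = ring_frac,
    nVessels = as.integer(n_vessels), vesselWidth = vessel_width,
    boundaryMargin = as.integer(boundary_margin)
  )
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d x %d (%g-%g nm), noise sd %g DN, tumor: %s\n",
    object@rows, object@cols, object@bands, object@wlRange[1],
    object@wlRange[2], object@noiseSd,
    if (object@tumorPresent) "yes" else "no"
  ))
})

.phantomWavelengths <- function(spec) {
  seq(spec@wlRange[1], spec@wlRange[2], length.out = spec@bands)
}

# draw the 4 class endmembers (percent reflectance) on the wavelength axis;
# uses the current RNG state. Each class gets an anchor Gaussian at a
# class-specific wavelength plus random minor components, which keeps the
# pairwise spectral angles comfortably apart; a retry loop enforces the
# configured minimum separation.
.drawEndmembers <- function(spec) {
  wl <- .phantomWavelengths(spec)
  span <- diff(spec@wlRange)
  anchors <- spec@wlRange[1] + span * c(0.25, 0.5, 0.7, 0.88)
  levels <- c(normal = 45, tumor = 38, vessel = 25, background = 78)
  for (attempt in seq_len(100L)) {
    em <- matrix(0, 4, spec@bands,
                 dimnames = list(names(.tissueCodes()), NULL))
    for (cl in 1:4) {
      g <- 1.2 * exp(-(wl - anchors[cl])^2 / (2 * (0.18 * span)^2))
      for (i in seq_len(spec@nGauss)) {
        mu <- runif(1, spec@wlRange[1], spec@wlRange[2])
        sg <- runif(1, 0.05, 0.2) * span
        g <- g + runif(1, 0.1, 0.5) * exp(-(wl - mu)^2 / (2 * sg^2))
      }
      g <- g / max(g)
      em[cl, ] <- levels[cl] * (0.25 + 0.75 * g)
    }
    angles <- utils::combn(4, 2, function(p) samAngle(em[p[1], ], em[p[2], ]))
    if (min(angles) >= spec@minSeparation) {
      attr(em, "pairwiseSAM") <- angles
      return(em)
    }
  }
  stop(sprintf(
    "could not draw endmembers with pairwise SAM >= %.3g rad in 100 tries",
    spec@minSeparation
  ))
}

#' Generate class endmember spectra
#'
#' Draws four smooth, non-negative class spectra (percent reflectance) on
#' the phantom's wavelength axis, with all pairwise spectral angles at
#' least `min_separation`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed RNG seed.
#' @return 4 x bands matrix (rows `normal`, `tumor`, `vessel`,
#'   `background`) with attribute `"pairwiseSAM"`.
#' @export
generateEndmembers <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withr::with_seed(seed, .drawEndmembers(spec))
}

# scene region layout (codes 1..4 over the full grid); uses current RNG
.drawLayout <- function(spec) {
  r <- spec@rows
  c_ <- spec@cols
  region <- matrix(classCodes()[["normal"]], r, c_)
  ring <- max(1L, ceiling(spec@ringFrac * min(r, c_)))
  region[c(seq_len(ring), r - seq_len(ring) + 1L), ] <-
    classCodes()[["background"]]
  region[, c(seq_len(ring), c_ - seq_len(ring) + 1L)] <-
    classCodes()[["background"]]
  rows_idx <- matrix(seq_len(r), r, c_)
  for (v in seq_len(spec@nVessels)) {
    r0 <- runif(1, 0.25, 0.75) * r
    amp <- runif(1, 0.05, 0.15) * r
    phase <- runif(1, 0, 2 * pi)
    centre <- r0 + amp * sin(2 * pi * seq_len(c_) / c_ + phase)
    hit <- abs(sweep(rows_idx, 2, centre)) <= spec@vesselWidth
    region[hit & region == classCodes()[["normal"]]] <-
      classCodes()[["vessel"]]
  }
  if (spec@tumorPresent && spec@tumorRadiusFrac > 0) {
    ctr <- c(runif(1, 0.35, 0.65) * r, runif(1, 0.35, 0.65) * c_)
    rad <- spec@tumorRadiusFrac * min(r, c_)
    dist2 <- outer(seq_len(r), seq_len(c_), function(i, j) {
      (i - ctr[1])^2 + (j - ctr[2])^2
    })
    region[dist2 <= rad^2] <- classCodes()[["tumor"]]
  }
  region
}

# truth labels: region codes with an unlabeled margin wherever another
# region lies within the boundary margin (surgeons label only reliable
# interior pixels)
.erodeTruth <- function(region, margin) {
  if (margin < 1L) return(region)
  r <- nrow(region)
  c_ <- ncol(region)
  keep <- matrix(TRUE, r, c_)
  for (di in -margin:margin) {
    for (dj in -margin:margin) {
      if (di == 0L && dj == 0L) next
      src_i <- pmin(pmax(seq_len(r) + di, 1L), r)
      src_j <- pmin(pmax(seq_len(c_) + dj, 1L), c_)
      keep <- keep & (region[src_i, src_j] == region)
    }
  }
  truth <- region
  truth[!keep] <- classCodes()[["unlabeled"]]
  truth
}

# build one scene with given endmembers; uses the current RNG state
.buildScene <- function(spec, endmembers, name = "phantom") {
  r <- spec@rows
  c_ <- spec@cols
  b <- spec@bands
  wl <- .phantomWavelengths(spec)
  region <- .drawLayout(spec)

  # reflectance field: class endmember with per-pixel amplitude jitter
  jit <- pmax(1 + rnorm(r * c_, sd = spec@jitterSd), 0.1)
  beta <- endmembers[as.vector(region), , drop = FALSE] * jit
  # white reference line: lamp-like band shape x smooth column gain
  lamp <- 0.6 + 0.4 * exp(-((wl - mean(spec@wlRange)) / (0.5 * diff(spec@wlRange)))^2)
  phase <- runif(1, 0, 2 * pi)
  gain <- 1 + spec@gainAmplitude * sin(pi * seq_len(c_) / c_ + phase)
  white_line <- array(0, c(1L, c_, b))
  white_line[1, , ] <- spec@darkLevel +
    (spec@whiteLevel - spec@darkLevel) * outer(gain, lamp)
  dark_line <- array(spec@darkLevel, c(1L, c_, b))
  if (spec@refNoiseSd > 0) {
    white_line <- white_line + rnorm(length(white_line), sd = spec@refNoiseSd)
    dark_line <- dark_line + rnorm(length(dark_line), sd = spec@refNoiseSd)
  }
  if (spec@deadPixelFraction > 0) {
    n_dead <- round(spec@deadPixelFraction * c_ * b)
    dead <- sample(c_ * b, n_dead)
    white_line[1, , ][dead] <- dark_line[1, , ][dead]
  }

  # raw DN by inverting the reflectance calibration, the white line
  # broadcast along the scan axis; sensor noise added on top
  white_full <- .broadcastRef(white_line, r)
  dark_full <- .broadcastRef(dark_line, r)
  wm <- matrix(white_full, r * c_, b)
  dm <- matrix(dark_full, r * c_, b)
  alpha <- dm + (wm - dm) * beta / 100
  if (spec@noiseSd > 0) {
    alpha <- alpha + rnorm(length(alpha), sd = spec@noiseSd)
  }

  # specular highlights: saturated pixels, left unlabeled in the truth map
  specular <- integer()
  if (spec@specularFraction > 0) {
    n_spec <- round(spec@specularFraction * r * c_)
    if (n_spec > 0) {
      specular <- sample(r * c_, n_spec)
      alpha[specular, ] <- spec@saturationDn
    }
  }
  alpha <- pmin(pmax(alpha, 0), spec@saturationDn)

  truth <- .erodeTruth(region, spec@boundaryMargin)
  if (length(specular)) truth[specular] <- classCodes()[["unlabeled"]]

  list(
    raw = HyperCube(array(alpha, c(r, c_, b)), wl, units = "raw",
                    name = name),
    refs = ReferenceFrames(white_line, dark_line, wavelengths = wl),
    truth = GoldStandardMap(labels = truth),
    reflectance = HyperCube(array(pmax(beta, 0), c(r, c_, b)), wl,
                            units = "reflectance_percent",
                            name = paste0(name, "_reflectance")),
    region = region,
    endmembers = endmembers
  )
}

#' Generate a synthetic intraoperative scene
#'
#' Builds one phantom acquisition: the raw digital-number cube (obtained by
#' inverting the reflectance calibration, so white/dark references and
#' illumination gain are folded in exactly), the matching pushbroom line
#' references, and the ground-truth label map with unlabeled region
#' boundaries.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed RNG seed (scene geometry, jitter, noise).
#' @param endmembers optional 4 x bands endmember matrix (e.g. a
#'   subject-specific one); drawn from `spec` when `NULL`.
#' @param name cube name.
#' @return A list with elements `raw` ([HyperCube-class]), `refs`
#'   ([ReferenceFrames-class]), `truth` ([GoldStandardMap-class]),
#'   `reflectance` (the noise-free reflectance [HyperCube-class]),
#'   `region` (full region-code matrix) and `endmembers`.
#' @export
#' @examples
#' sc <- generateScene(phantomSpec(rows = 24, cols = 24, bands = 30), seed = 7)
#' sc$raw
generateScene <- function(spec, seed = 1L, endmembers = NULL,
                          name = "phantom") {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  withr::with_seed(seed, {
    if (is.null(endmembers)) endmembers <- .drawEndmembers(spec)
    .buildScene(spec, endmembers, name = name)
  })
}

# smooth relative spectral offset curve for one subject (current RNG)
.subjectOffset <- function(spec) {
  wl <- .phantomWavelengths(spec)
  span <- diff(spec@wlRange)
  g <- numeric(spec@bands)
  for (i in 1:3) {
    mu <- runif(1, spec@wlRange[1], spec@wlRange[2])
    sg <- runif(1, 0.1, 0.3) * span
    g <- g + rnorm(1) * exp(-(wl - mu)^2 / (2 * sg^2))
  }
  if (sd(g) > 0) g <- g / sd(g)
  spec@subjectSd * g
}

#' Generate a multi-subject phantom training campaign
#'
#' Emulates a labeled data-acquisition campaign: each subject gets its own
#' smooth spectral offset applied to the shared class endmembers, one scene
#' per subject is synthesized, calibrated and pre-processed, and the
#' ground-truth labeled pixels (subsampled per class) are assembled into a
#' [TrainingDataset-class] whose `groups` carry the subject ids. Additional
#' held-out scenes (new subjects, never contributing training rows) are
#' returned for end-to-end evaluation.
#'
#' @param spec a [PhantomSpec-class].
#' @param n_subjects number of training subjects (>= 2).
#' @param seed RNG seed.
#' @param config [PreprocessConfig-class] applied before extracting
#'   spectra.
#' @param max_per_class per-class, per-subject cap on extracted training
#'   pixels (default 400).
#' @param n_holdout held-out scenes (default 1).
#' @return A list with `dataset` ([TrainingDataset-class]), `holdout`
#'   (list of scene lists as from [generateScene()]) and `endmembers`.
#' @export
generateDataset <- function(spec, n_subjects = 4L, seed = 1L,
                            config = preprocessConfig(),
                            max_per_class = 400L, n_holdout = 1L) {
  stopifnot(is(spec, "PhantomSpec"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  withr::with_seed(seed, {
    endmembers <- .drawEndmembers(spec)
    pairs <- list()
    for (s in seq_len(n_subjects)) {
      offs <- .subjectOffset(spec)
      em_s <- pmax(endmembers * rep(1 + offs, each = 4), 0.1)
      scene <- .buildScene(spec, em_s, name = sprintf("subject%02d", s))
      cal <- calibrate(scene$raw, scene$refs)
      pp <- preprocess(cal$cube, config)
      labels <- labelMatrix(scene$truth)
      # per-class subsample of the labeled truth pixels
      keep <- unlist(lapply(.tissueCodes(), function(code) {
        pool <- which(labels == code)
        if (length(pool) > max_per_class) {
          sample(pool, max_per_class)
        } else {
          pool
        }
      }))
      sub <- matrix(0L, spec@rows, spec@cols)
      sub[keep] <- labels[keep]
      pairs[[s]] <- list(cube = pp, map = GoldStandardMap(labels = sub),
                         subject = sprintf("subject%02d", s))
    }
    holdout <- lapply(seq_len(n_holdout), function(h) {
      offs <- .subjectOffset(spec)
      em_h <- pmax(endmembers * rep(1 + offs, each = 4), 0.1)
      .buildScene(spec, em_h, name = sprintf("holdout%02d", h))
    })
    list(dataset = assembleDataset(pairs), holdout = holdout,
         endmembers = endmembers)
  })
}
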