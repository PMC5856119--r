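---
title: "Methods: intraoperative hyperspectral tumor delineation with hsbrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intraoperative hyperspectral tumor delineation with hsbrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsbrain)
```

## The problem

During brain tumor resection the surgeon cannot reliably tell tumor from
normal parenchyma by eye, and preoperative imaging loses registration as
the brain shifts. Visible/near-infrared (VNIR, 400–1000 nm) hyperspectral
imaging offers a label-free alternative: a pushbroom camera records a full
reflectance spectrum per pixel, and tissue classes — normal tissue, tumor,
blood vessels/hypervascularized tissue, and non-tissue background — differ
in their spectral signatures. `hsbrain` implements the complete processing
chain from a raw acquisition to a four-class delineation map, together
with the labeling tooling used to build training data and a synthetic
phantom generator so that every stage can be exercised and validated
without clinical data.

The in-situ stage graph is:

```
raw cube + white/dark refs
  -> calibration -> pre-processing -> +-> PCA -> SVM -> k-NN filter -+
                                      |                              +-> majority vote -> TMD map
                                      +-> hierarchical K-means ------+
```

The supervised arm (PCA, SVM, k-NN) and the unsupervised arm (hierarchical
K-means) are independent and join only at the majority-voting fusion; the
package executes them sequentially in a single process but preserves the
logical stage separation, and `runPipeline()` reports wall time per stage
(`pre_processing`, `pca_svm`, `knn`, `hkm`, `mv`, plus `calibration` and
`tmd`).

## Reflectance calibration

Raw digital numbers depend on illumination and sensor gain. With a white
reference capture $\gamma$ (a ~99% reflective tile imaged in the surgical
illumination) and a dark reference $\delta$ (shutter closed), the percent
reflectance of a raw cube $\alpha$ is

$$\beta = 100\,\frac{\alpha - \delta}{\gamma - \delta}.$$

Because a pushbroom system images one line at a time, a single reference
line (1 × cols × bands) is accepted and broadcast along the scan axis.
Design choices where the published pipelines are silent:

* samples with $\gamma \le \delta$ (dead reference samples) produce 0 and
  flag the pixel in a returned mask rather than NaN;
* negative reflectance from sensor noise ($\alpha < \delta$) is clipped to
  0, because the downstream unit-max/unit-area normalizations assume
  non-negative spectra;
* values above 100% (specular highlights off the arachnoid or surgical
  serum) are **kept** and flagged separately — bright pixels must remain
  classifiable as background, which is how real systems dispose of glints.

`calibrate()` satisfies two identities that the test suite checks
exactly: $\beta(\alpha{=}\delta) = 0$, $\beta(\alpha{=}\gamma) = 100$, and
gain invariance — rescaling the dark-subtracted signal and white reference
by any common positive factor leaves $\beta$ unchanged.

## Pre-processing chain

The published processing chains "homogenize" spectral signatures without
enumerating the steps, so the chain here is defined explicitly and kept
configurable (`preprocessConfig()`), applied in a fixed order:

1. **Band clip** to 450–900 nm (default): discards the noisy extremes of
   the 400–1000 nm axis where CCD quantum efficiency collapses.
2. **Spectral smoothing** along the band axis: 5-band moving average by
   default (Savitzky–Golay optional), edges replicated. Window 1 disables.
3. **Band averaging** to 128 bands (default): contiguous groups of equal
   size are averaged, taming dimensionality (~10⁶ values per small scene)
   while preserving the smooth spectral shape.
4. **Per-pixel normalization**: unit-max by default, making signatures
   comparable across illumination levels. `unit_area`, `standardize` and
   `none` are available; all-zero (or constant, for `standardize`) spectra
   are left untouched and flagged.

Unit-max normalization is scale-only, so spectral angles (next section)
are unchanged by it — a cross-module property in the test suite.

## SAM labeling and the training dataset

Gold-standard maps are built the way surgeons build them: pick a trusted
reference pixel (e.g. over a biopsy-confirmed marker), highlight all
pixels within a spectral-angle threshold, and assign them to a class.
The spectral angle mapper (SAM) between spectra $x, y$ is the angle
between them as vectors; it ignores illumination intensity. `samAngle()`
evaluates it through the chord length of the unit vectors,
$2\arcsin(\lVert \hat x - \hat y\rVert/2)$, which returns exactly 0 for
proportional spectra where the plain arc-cosine is limited to
$\sqrt{\varepsilon}$ accuracy.

`samSelect()` masks are monotone in the threshold (nested masks), the
reference pixel is always selected, and all-zero pixels never are.
`assignClass()` refuses to overwrite existing labels unless explicitly
told to — relabeling confirmed pixels should never happen silently.
Thresholds come from configuration or the command line; the interactive
slider of the original labeling GUI is out of scope.

`assembleDataset()` gathers one row per labeled pixel with its subject
identifier (for grouped cross-validation) and optional tumor-subtype
annotation; `datasetSummary()` reproduces campaign bookkeeping (per-class
and per-subtype counts, with the total always equal to the row count).
SAM labeling operates on pre-processed spectra by default, matching the
pre-processed signatures used downstream; raw-reflectance labeling is
possible by passing an uncalibrated/unprocessed cube.

## Supervised stage

* **Classifier.** A multi-class SVM (one-vs-one, pairwise-coupling
  probability estimates) via `e1071`/libsvm. The kernel is linear with
  $C = 1$ by default: with hundreds of bands and a few thousand training
  pixels the problem is high-dimensional and close to separable, where a
  linear machine is the defensible default and radial kernels mostly add
  hyper-parameters. Both are configurable. Training rows are canonically
  sorted (label, then spectra lexicographically) and the RNG seeded, so a
  fit is deterministic and invariant to row permutations — libsvm's
  internal Platt-scaling cross-validation otherwise depends on row order.
* **One-band guide.** `pcaFirstComponent()` projects each pixel spectrum
  onto the first principal axis of the image's own mean-centred
  pixel-spectra covariance. PCA is fitted per image, not on the training
  set: the guide only needs to express within-scene contrast, and the
  incoming scene is always available at run time. The loading sign is
  fixed (largest-magnitude entry positive) so results are reproducible.
* **k-NN probability filter.** Each pixel is embedded as
  $(\lambda r/s,\ \lambda c/s,\ g)$ with $s = \max(\text{rows},
  \text{cols})$, $g$ the min–max-scaled guide value, and its probability
  vector replaced by the mean over its $K$ nearest neighbors (itself
  included), then renormalized. Defaults $K = 40$, $\lambda = 1$ balance
  the spatial and photometric terms; $K = 1$ is the identity, large
  $\lambda$ tends to a purely spatial mean filter and $\lambda = 0$ to a
  guide-value-only filter (both limits are tested against brute-force
  oracles). The neighbor search is exact brute force in C++ with a
  deterministic tie-break (distance, then pixel index).

`trainingFractionCurve()` reproduces the training-set-size experiment:
class-stratified subsampling at each fraction followed by k-fold
cross-validation (10-fold by default), seeded and deterministic. On
phantom campaigns the curve plateaus at the full-data accuracy, i.e. no
overfitting as data grow.

## Unsupervised stage and fusion

"Hierarchical K-means" is implemented as bisecting K-means: start with
one cluster holding every pixel spectrum and repeatedly split the cluster
with the largest within-cluster sum of squares via 2-means (10 restarts,
centers drawn from distinct unique spectra) until $K$ clusters exist.
Bisecting K-means is the standard reading of hierarchical K-means and
gives a deterministic, testable structure; on 6-point toys the K = 2
result matches the exhaustive 2-partition optimum. $K = 24$ by default —
the published value is not stated, and 24 clusters comfortably
oversegment a four-class scene so that the fusion step, not the
segmentation, decides class boundaries.

Fusion assigns each cluster the class densities of its pixels' filtered
argmax labels (hard counts by default; a `soft = TRUE` switch averages
probability vectors instead — the published description fuses a
classification *map*, i.e. labels, which is why hard counts are the
default). The majority vote takes the maximum-density class with ties
broken tumor > vessel > normal > background: missing tumor is the costly
error, so the tie rule is clinically conservative. The three-maximum-
density (TMD) map keeps each cluster's three largest densities,
renormalizes them to sum 1 and blends the class colors (tumor red, normal
green, vessel blue, background black or white) as a convex combination —
the blend formula behind the published renderings is not stated, and the
convex combination is this package's choice. Pure clusters therefore
render in pure class colors, and every rendered color lies in the convex
hull of the class colors.

## The phantom generator

`phantomSpec()`/`generateScene()` synthesize scenes with the statistical
structure the pipeline assumes, in the **raw digital-number domain** so
that calibration is exercised too (the reflectance field is pushed through
the inverse of the calibration equation using the generated references):

* four smooth, non-negative class endmembers (anchor Gaussian per class
  plus random minor components) with all pairwise spectral angles at
  least 0.15 rad by default — comparable to the separation visible
  between real tissue-class signatures after pre-processing;
* a scene layout of background ring, normal parenchyma, sinuous vessel
  curves and one tumor blob (omit with `tumor_present = FALSE`);
* intra-subject variability as per-pixel amplitude jitter (sd 0.02),
  inter-subject variability as smooth per-subject spectral offsets
  (sd 0.04) in `generateDataset()`;
* a 12-bit sensor scale (dark ~100 DN, white ~3500 DN, saturation
  4095 DN) with additive sensor noise (sd 20 DN), reference-capture noise
  (sd 2 DN), a smooth illumination gain along the line axis folded into
  the white reference, an optional fraction of dead reference samples,
  and a small fraction (0.2%) of saturated specular pixels;
* ground-truth maps label only region interiors (2 px erosion margin) and
  never specular pixels, mirroring labeling practice of marking only a
  few reliable pixels.

With all noise terms at zero, calibrating a generated scene recovers the
reflectance field to machine precision — the generator and the
calibration are exact inverses. Increasing sensor noise monotonically
degrades classification accuracy (tested at three levels, five seeds
each, on means), and pooled cross-validation on multi-subject campaigns
is at least as optimistic as leave-one-subject-out, confirming that the
inter-subject structure actually leaks when folds ignore subjects.

**What the phantom does not emulate:** optical tissue physics
(absorption/scattering), spatially correlated noise, motion or focus
artifacts, real glioma heterogeneity, or the near-infrared range. Passing
phantom tests therefore validates the *algorithmic chain* — calibration
algebra, normalization, classifier mechanics, filtering, clustering and
fusion — not clinical performance, which requires patient data this
package deliberately does not contain.

## Numerical and interface choices

* Coordinates are R-native: 1-based `(row, col, band)`, origin top-left;
  cluster ids run 1..K. All user-facing indices follow this convention.
* ENVI (text header + headerless binary raster) is the interchange
  format, the de-facto dialect of pushbroom camera tooling; storage
  orders bsq/bil/bip, both byte orders and the common data types are
  supported, with `float64` the write default so round trips are
  bit-identical. The wavelength list is mandatory on read.
* `spatialExtentMm()` rounds half-up, matching the printed scene extents
  (1004 × 1787 px at 128.7 µm ↦ 129 × 230 mm).
* Argmax ties in probability maps resolve to the lowest class code;
  k-NN neighbor ties resolve by pixel index; equidistant wavelength
  targets resolve to the lower band index. Every stochastic element
  (endmember draws, jitter, SVM calibration folds, 2-means restarts,
  subsampling, fold assignment) is governed by an explicit seed.
* Scene sizes used by the test and acceptance runs are a package choice:
  module tests use 32 × 32 × 48 phantoms, the end-to-end recovery runs
  three 128 × 128 × 300 scenes (128 bands after pre-processing), and the
  ten-seed tumor-free negative control uses 64 × 64 scenes.

## Worked example

```{r example, eval = FALSE}
spec  <- phantomSpec()                      # 128 x 128 x 300 scene
camp  <- generateDataset(spec, n_subjects = 4, seed = 11)
model <- trainClassifier(camp$dataset, seed = 1)

scene <- generateScene(spec, seed = 99, endmembers = camp$endmembers)
res   <- runPipeline(scene$raw, scene$refs, model, pipelineConfig(seed = 7))

truth <- labelMatrix(scene$truth)
lab   <- which(truth != 0)
mean(res$voteMap[lab] == truth[lab])        # pixel agreement on labeled truth
writeRGBPng(res$tmd, "tmd.png")             # tumor rendered in red
```

## Known limitations

* The brute-force k-NN filter is O(n²) in pixels; scenes much beyond
  ~10⁵ pixels call for an approximate or tree-based neighbor search.
* The probabilistic SVM calibrates probabilities by internal
  cross-validation; on very small training sets the probability estimates
  (not the class boundaries) can be coarse.
* Bisecting K-means is greedy; it matches the global optimum on small
  separable toys but is not guaranteed to elsewhere, which is the usual
  trade-off accepted for hierarchical K-means segmentation.
* The four-class scheme pools all tumor subtypes into one class; the
  dataset structures carry subtype annotations, but no per-subtype
  classifier is provided.
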