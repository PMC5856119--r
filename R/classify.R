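## Spatial-spectral supervised stage: probabilistic SVM, first-principal-
## component guide image, and k-NN filtering of the probability maps.

#' ClassifierModel: a trained probabilistic SVM
#'
#' Wraps a fitted multi-class support vector machine (one-vs-one with
#' pairwise-coupling probability estimates) together with its class-code
#' order and training configuration.
#'
#' @slot fit the fitted [e1071::svm] object.
#' @slot classOrder integer class codes, in the order of the probability
#'   output.
#' @slot bands number of spectral features the model expects.
#' @slot config list of training settings (kernel, cost, seed).
#'
#' @aliases ClassifierModel-class
#' @export
setClass("ClassifierModel",
  representation(fit = "ANY", classOrder = "integer", bands = "integer",
                 config = "list")
)

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf(
    "ClassifierModel: %s SVM (C = %g), %d classes, %d bands\n",
    object@config$kernel, object@config$cost,
    length(object@classOrder), object@bands
  ))
})

# canonical row order (label, then spectra lexicographically): libsvm's
# internal probability-calibration CV depends on row order, so sorting
# makes training invariant to input permutations
.canonicalOrder <- function(spectra, labels) {
  keys <- c(list(labels), lapply(seq_len(ncol(spectra)),
                                 function(j) spectra[, j]))
  do.call(order, keys)
}

#' Train the supervised tissue classifier
#'
#' Fits a multi-class probabilistic SVM (linear kernel by default,
#' one-vs-one with pairwise-coupling probability estimates) on a labeled
#' training dataset. Training rows are canonically sorted and the RNG seed
#' fixed, so the fit is deterministic and invariant to row permutations.
#'
#' @param ds a [TrainingDataset-class] with at least 2 classes and at
#'   least 2 samples per class.
#' @param kernel SVM kernel (default `"linear"`, the defensible choice for
#'   high-dimensional spectra).
#' @param cost soft-margin cost C (default 1).
#' @param seed RNG seed for the internal probability-calibration folds.
#' @return A [ClassifierModel-class].
#' @export
trainClassifier <- function(ds, kernel = "linear", cost = 1, seed = 1L) {
  stopifnot(is(ds, "TrainingDataset"))
  tab <- table(ds@labels)
  if (length(tab) < 2L) {
    stop("training requires at least 2 classes (got ", length(tab), ")")
  }
  if (any(tab < 2L)) {
    stop("every class needs at least 2 training samples")
  }
  ord <- .canonicalOrder(ds@spectra, ds@labels)
  x <- ds@spectra[ord, , drop = FALSE]
  y <- factor(ds@labels[ord], levels = sort(unique(ds@labels)))
  fit <- withr::with_seed(seed, e1071::svm(
    x = x, y = y, kernel = kernel, cost = cost,
    probability = TRUE, scale = FALSE
  ))
  new("ClassifierModel",
    fit = fit, classOrder = as.integer(levels(y)),
    bands = ncol(x), config = list(kernel = kernel, cost = cost, seed = seed)
  )
}

#' Pixel-wise class probabilities for a cube
#'
#' Applies the trained SVM to every pixel spectrum of a (pre-processed)
#' cube and returns the per-pixel class-probability field. The cube must
#' have been pre-processed with the same chain as the training spectra.
#'
#' @param model a [ClassifierModel-class].
#' @param cube a [HyperCube-class] whose band count matches the model.
#' @return A [ProbabilityMap-class] (per-pixel probabilities sum to 1).
#' @export
predictProbabilities <- function(model, cube) {
  stopifnot(is(model, "ClassifierModel"), is(cube, "HyperCube"))
  d <- dim(cube@data)
  if (d[3] != model@bands) {
    stop(sprintf(
      "band-count mismatch: model expects %d bands, cube has %d",
      model@bands, d[3]
    ))
  }
  x <- .pixelMatrix(cube)
  pred <- predict(model@fit, x, probability = TRUE)
  pm <- attr(pred, "probabilities")
  pm <- pm[, as.character(model@classOrder), drop = FALSE]
  pm <- pm / rowSums(pm)
  ProbabilityMap(array(pm, c(d[1], d[2], ncol(pm))),
                 classOrder = model@classOrder)
}

#' First-principal-component image of a cube
#'
#' Projects every pixel spectrum onto the first principal axis of the
#' mean-centred pixel-spectra covariance, yielding the one-band
#' representation used to guide spatial-spectral filtering. The loading
#' vector's sign is fixed so that its largest-magnitude entry is positive.
#'
#' @param cube a [HyperCube-class] with at least 2 bands and non-zero
#'   spectral variance.
#' @return rows x cols numeric matrix of PC1 scores, with attribute
#'   `"varianceExplained"` (fraction of total variance).
#' @export
pcaFirstComponent <- function(cube) {
  stopifnot(is(cube, "HyperCube"))
  x <- .pixelMatrix(cube)
  if (sum(apply(x, 2, sd) > 0) == 0) {
    stop("cube is constant: the principal axis is undefined")
  }
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  loading <- pr$rotation[, 1]
  scores <- pr$x[, 1]
  if (loading[which.max(abs(loading))] < 0) {
    loading <- -loading
    scores <- -scores
  }
  d <- dim(cube@data)
  out <- matrix(scores, d[1], d[2])
  attr(out, "varianceExplained") <- pr$sdev[1]^2 / sum(pr$sdev^2)
  attr(out, "loading") <- loading
  out
}

#' Spatial-spectral k-NN filtering of a probability map
#'
#' Homogenizes a pixel-wise probability field using the scene's spatial
#' structure: each pixel is embedded as
#' `(lambda * row / s, lambda * col / s, guide)` with `s = max(rows, cols)`
#' and the guide image min-max scaled to `[0, 1]`, and its probability
#' vector is replaced by the mean over its K nearest neighbors in that
#' feature space (the pixel itself included), then renormalized to sum 1.
#' `K = 1` is the identity; large `lambda` approaches a purely spatial
#' mean filter, `lambda = 0` a guide-value-only filter.
#'
#' @param probs a [ProbabilityMap-class].
#' @param guide rows x cols numeric guide image (typically
#'   [pcaFirstComponent()]).
#' @param K number of neighbors (default 40); must not exceed the pixel
#'   count.
#' @param lambda spatial weight >= 0 (default 1).
#' @return The filtered [ProbabilityMap-class].
#' @export
knnFilter <- function(probs, guide, K = 40L, lambda = 1) {
  stopifnot(is(probs, "ProbabilityMap"))
  d <- dim(probs@probs)
  if (!identical(dim(guide), d[1:2])) {
    stop("guide image shape does not match the probability map")
  }
  n <- d[1] * d[2]
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K exceeds the pixel count")
  if (lambda < 0) stop("lambda must be >= 0")
  s <- max(d[1], d[2])
  g <- as.vector(guide)
  rng <- range(g)
  g <- if (rng[2] > rng[1]) (g - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  grid <- matrix(seq_len(n), d[1], d[2])
  feats <- cbind(
    lambda * as.vector(row(grid)) / s,
    lambda * as.vector(col(grid)) / s,
    g
  )
  pm <- matrix(probs@probs, n, d[3])
  out <- knn_mean_probs(feats, pm, K)
  out <- out / rowSums(out)
  ProbabilityMap(array(out, d), classOrder = probs@classOrder)
}

#' Accuracy as a function of training-set size
#'
#' Reproduces the training-fraction experiment: for each fraction, a
#' class-stratified subsample of the dataset is drawn and its mean overall
#' accuracy estimated by k-fold cross-validation. Fractions so small that
#' a class vanishes are skipped with a warning. Deterministic given
#' `seed`.
#'
#' @param ds a [TrainingDataset-class].
#' @param fractions numeric vector in `(0, 1]`.
#' @param folds number of CV folds (>= 2; default 10).
#' @param seed RNG seed governing subsampling and fold assignment.
#' @param kernel,cost SVM settings passed to the per-fold fits.
#' @return Data frame with columns `fraction`, `n` (subsample size) and
#'   `accuracy` (mean overall accuracy across folds; `NA` for skipped
#'   fractions).
#' @export
trainingFractionCurve <- function(ds, fractions = seq(0.1, 1, by = 0.1),
                                  folds = 10L, seed = 1L,
                                  kernel = "linear", cost = 1) {
  stopifnot(is(ds, "TrainingDataset"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  labels <- ds@labels
  classes <- sort(unique(labels))
  withr::with_seed(seed, {
    res <- lapply(fractions, function(f) {
      idx <- unlist(lapply(classes, function(cl) {
        pool <- which(labels == cl)
        k <- round(f * length(pool))
        if (k < 1L) return(integer())
        sample(pool, k)
      }))
      sub_lab <- labels[idx]
      if (length(unique(sub_lab)) < length(classes)) {
        warning(sprintf(
          "fraction %.3g drops at least one class entirely; skipped", f
        ))
        return(data.frame(fraction = f, n = length(idx), accuracy = NA_real_))
      }
      x <- ds@spectra[idx, , drop = FALSE]
      y <- factor(sub_lab, levels = classes)
      fold_id <- integer(length(idx))
      for (cl in classes) {
        w <- which(sub_lab == cl)
        fold_id[w] <- sample(rep(seq_len(folds), length.out = length(w)))
      }
      acc <- vapply(seq_len(folds), function(k) {
        tr <- fold_id != k
        if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                          kernel = kernel, cost = cost, scale = FALSE)
        mean(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
      data.frame(fraction = f, n = length(idx),
                 accuracy = mean(acc, na.rm = TRUE))
    })
    do.call(rbind, res)
  })
}
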