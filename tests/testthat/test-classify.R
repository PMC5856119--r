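toyDataset <- function(n_per = 10, bands = 5, classes = c(1L, 2L), sep = 4) {
  set.seed(99)
  sp <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(rnorm(n_per * bands, mean = i * sep), n_per)
  }))
  TrainingDataset(sp, rep(classes, each = n_per))
}

test_that("training enforces class structure and separates a linear toy", {
  ds <- toyDataset()
  model <- trainClassifier(ds, seed = 2)
  pred_cube <- spectraCube(ds@spectra, nSignatures(ds), 1,
                           wl = seq_len(ncol(ds@spectra)))
  probs <- predictProbabilities(model, pred_cube)
  expect_equal(as.vector(argmaxMap(probs)), as.vector(ds@labels))

  solo <- TrainingDataset(matrix(rnorm(20), 10), rep(1L, 10))
  expect_error(trainClassifier(solo), "2 classes")
  thin <- TrainingDataset(matrix(rnorm(8), 4), c(1L, 1L, 1L, 2L))
  expect_error(trainClassifier(thin), "2 training samples")
})

test_that("training is invariant to row permutations given the seed", {
  ds <- toyDataset(n_per = 15, bands = 6)
  set.seed(123)
  perm <- sample(nSignatures(ds))
  ds_perm <- TrainingDataset(ds@spectra[perm, ], ds@labels[perm],
                             ds@groups[perm])
  m1 <- trainClassifier(ds, seed = 7)
  m2 <- trainClassifier(ds_perm, seed = 7)
  cube <- spectraCube(matrix(rnorm(12 * 6, mean = 6), 12), 4, 3,
                      wl = seq_len(6))
  expect_equal(probArray(predictProbabilities(m1, cube)),
               probArray(predictProbabilities(m2, cube)),
               tolerance = 1e-12)
})

test_that("probability maps are normalized and match exemplars in-class", {
  ds <- toyDataset(n_per = 12, bands = 4, sep = 6)
  model <- trainClassifier(ds)
  cube <- spectraCube(ds@spectra, 6, 4, wl = 1:4)
  probs <- predictProbabilities(model, cube)
  sums <- apply(probArray(probs), c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(probArray(probs) >= 0))

  wrong <- tinyCube(2, 2, 7, wl = 1:7)
  expect_error(predictProbabilities(model, wrong), "band-count")
})

test_that("PC1 matches the closed-form eigen-decomposition oracle", {
  # 2-band toy: three collinear points
  sp <- rbind(c(1, 1), c(2, 2), c(3, 3))
  cube <- spectraCube(sp, 3, 1, wl = c(1, 2))
  pc1 <- pcaFirstComponent(cube)
  # oracle: eigen-decomposition of the 2x2 covariance
  cov2 <- stats::cov(sp)
  eig <- eigen(cov2, symmetric = TRUE)
  v <- eig$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  oracle <- sweep(sp, 2, colMeans(sp)) %*% v
  expect_equal(as.vector(pc1), as.vector(oracle), tolerance = 1e-9)
  expect_equal(as.vector(pc1), c(-sqrt(2), 0, sqrt(2)), tolerance = 1e-9)
  expect_equal(attr(pc1, "varianceExplained"), 1, tolerance = 1e-12)

  # sign convention is stable when every pixel is duplicated
  dup <- spectraCube(rbind(sp, sp), 6, 1, wl = c(1, 2))
  pc_dup <- pcaFirstComponent(dup)
  expect_equal(attr(pc_dup, "loading"), attr(pc1, "loading"),
               tolerance = 1e-9)

  expect_error(pcaFirstComponent(spectraCube(matrix(1, 4, 3), 2, 2, wl = 1:3)),
               "constant")
})

test_that("PC1 of a rank-1 cube explains all variance", {
  set.seed(5)
  v <- runif(6)
  scales <- runif(12, 0.5, 3)
  cube <- spectraCube(outer(scales, v), 4, 3, wl = 1:6)
  pc1 <- pcaFirstComponent(cube)
  expect_equal(attr(pc1, "varianceExplained"), 1, tolerance = 1e-12)
})

test_that("knnFilter equals a brute-force neighbor oracle on a 3x3 grid", {
  set.seed(11)
  probs <- array(runif(9 * 4), c(3, 3, 4))
  probs <- ProbabilityMap(probs / rep(apply(probs, c(1, 2), sum), 4),
                          classOrder = 1:4)
  guide <- matrix(runif(9), 3, 3)
  K <- 3
  lambda <- 0.8
  filtered <- knnFilter(probs, guide, K = K, lambda = lambda)

  # independent O(n^2) oracle
  s <- 3
  g <- as.vector(guide)
  g <- (g - min(g)) / (max(g) - min(g))
  grid <- matrix(1:9, 3, 3)
  feats <- cbind(lambda * as.vector(row(grid)) / s,
                 lambda * as.vector(col(grid)) / s, g)
  pm <- matrix(probArray(probs), 9, 4)
  oracle <- t(vapply(1:9, function(i) {
    d2 <- colSums((t(feats) - feats[i, ])^2)
    d2[i] <- -1
    nb <- order(d2)[seq_len(K)]
    v <- colMeans(pm[nb, , drop = FALSE])
    v / sum(v)
  }, numeric(4)))
  expect_equal(matrix(probArray(filtered), 9, 4), oracle, tolerance = 1e-9)
})

test_that("knnFilter limits: identity at K = 1, invariance on uniform maps", {
  set.seed(4)
  probs <- uniformProbMap(4, 5)
  guide <- matrix(runif(20), 4, 5)
  out <- knnFilter(probs, guide, K = 7, lambda = 1)
  expect_equal(probArray(out), probArray(probs), tolerance = 1e-12)

  random <- array(runif(20 * 4), c(4, 5, 4))
  random <- ProbabilityMap(random / rep(apply(random, c(1, 2), sum), 4),
                           classOrder = 1:4)
  expect_equal(probArray(knnFilter(random, guide, K = 1)),
               probArray(random), tolerance = 1e-12)

  expect_error(knnFilter(random, guide, K = 21), "exceeds")
  expect_error(knnFilter(random, matrix(0, 2, 2), K = 1), "shape")
  expect_error(knnFilter(random, guide, K = 2, lambda = -1), "lambda")
})

test_that("lambda sweeps between guide-only and purely spatial filtering", {
  set.seed(8)
  rows <- 4; cols <- 4; n <- rows * cols
  probs_arr <- array(runif(n * 4), c(rows, cols, 4))
  probs_arr <- probs_arr / rep(apply(probs_arr, c(1, 2), sum), 4)
  probs <- ProbabilityMap(probs_arr, classOrder = 1:4)
  pm <- matrix(probs_arr, n, 4)

  # lambda = 0 with a two-valued guide and K = group size: each pixel's
  # K nearest are exactly its own guide group (distance 0), so the output
  # is the group mean regardless of tie handling
  guide <- matrix(rep(c(0, 1), each = n / 2), rows, cols)
  out0 <- knnFilter(probs, guide, K = n / 2, lambda = 0)
  o0 <- matrix(probArray(out0), n, 4)
  for (v in c(0, 1)) {
    idx <- which(as.vector(guide) == v)
    grp_mean <- colMeans(pm[idx, , drop = FALSE])
    grp_mean <- grp_mean / sum(grp_mean)
    for (i in idx) expect_equal(o0[i, ], grp_mean, tolerance = 1e-9)
  }

  # very large lambda: the guide term is negligible and filtering becomes a
  # purely spatial mean. On a 2 x 2 grid with K = 3 every pixel's neighbor
  # set is itself plus its two edge-adjacent pixels, with no tie ambiguity.
  p2 <- array(runif(4 * 4), c(2, 2, 4))
  p2 <- ProbabilityMap(p2 / rep(apply(p2, c(1, 2), sum), 4), classOrder = 1:4)
  pm2 <- matrix(probArray(p2), 4, 4)
  big <- knnFilter(p2, matrix(runif(4), 2, 2), K = 3, lambda = 1e7)
  adjacency <- list(c(1, 2, 3), c(2, 1, 4), c(3, 1, 4), c(4, 2, 3))
  for (i in 1:4) {
    o <- colMeans(pm2[adjacency[[i]], , drop = FALSE])
    expect_equal(matrix(probArray(big), 4, 4)[i, ], o / sum(o),
                 tolerance = 1e-6)
  }
})

test_that("the training-fraction curve is deterministic and well-formed", {
  spec <- smallPhantomSpec()
  gd <- generateDataset(spec, n_subjects = 2, seed = 31,
                        config = smallChain(), max_per_class = 60)
  fr <- c(0.25, 0.5, 1.0)
  c1 <- trainingFractionCurve(gd$dataset, fractions = fr, folds = 4,
                              seed = 11)
  c2 <- trainingFractionCurve(gd$dataset, fractions = fr, folds = 4,
                              seed = 11)
  expect_identical(c1, c2)
  expect_equal(c1$fraction, fr)
  expect_true(all(c1$accuracy >= 0 & c1$accuracy <= 1))

  expect_error(trainingFractionCurve(gd$dataset, fractions = c(0, 0.5)),
               "fractions")
  expect_error(trainingFractionCurve(gd$dataset, folds = 1), "folds")

  # 2-fold CV on a 4-sample balanced toy runs without error
  toy <- TrainingDataset(matrix(c(0, 0, 10, 10, 0, 0, 10, 10), 4),
                         c(1L, 1L, 2L, 2L))
  out <- trainingFractionCurve(toy, fractions = 1, folds = 2, seed = 1)
  expect_equal(nrow(out), 1)

  # fractions that drop a class are skipped with a warning
  skew <- TrainingDataset(rbind(matrix(0, 40, 2), matrix(10, 2, 2)),
                          c(rep(1L, 40), rep(2L, 2)))
  expect_warning(
    res <- trainingFractionCurve(skew, fractions = 0.1, folds = 2, seed = 1),
    "drops"
  )
  expect_true(is.na(res$accuracy))
})
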