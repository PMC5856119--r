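test_that("samAngle is a scale-invariant angle in [0, pi]", {
  expect_equal(samAngle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(samAngle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(samAngle(c(1, 2), c(2, 4)), 0, tolerance = 1e-7)
  expect_equal(samAngle(c(1, 0), c(-1, 0)), pi)
  expect_error(samAngle(c(0, 0), c(1, 1)), "zero")
  expect_error(samAngle(1:3, 1:4), "length")
  set.seed(1)
  for (i in 1:20) {
    x <- runif(10)
    y <- runif(10)
    a <- samAngle(x, y)
    expect_gte(a, 0)
    expect_lte(a, pi)
    expect_equal(samAngle(3.7 * x, y), a, tolerance = 1e-12)
    expect_equal(samAngle(x, 0.01 * y), a, tolerance = 1e-12)
  }
})

test_that("samSelect behaves at the threshold limits", {
  # pixel 3 is an exact positive multiple of the reference; others differ
  sp <- rbind(c(1, 2, 3), c(3, 1, 1), c(2, 4, 6), c(0, 0, 0))
  cube <- spectraCube(sp, 2, 2, wl = c(1, 2, 3))
  # tiny threshold: only pixels proportional to the reference
  m <- samSelect(cube, c(1, 1), 1e-9)
  expect_identical(as.vector(m), c(TRUE, FALSE, TRUE, FALSE))
  # threshold >= pi: every non-zero pixel
  m2 <- samSelect(cube, c(1, 1), pi)
  expect_identical(as.vector(m2), c(TRUE, TRUE, TRUE, FALSE))

  expect_error(samSelect(cube, c(2, 2), 0.1), "zero")
  expect_error(samSelect(cube, c(9, 9), 0.1), "outside")
  expect_error(samSelect(cube, c(1, 1), 0), "positive")
})

test_that("samSelect is monotone in the threshold", {
  set.seed(3)
  cube <- spectraCube(matrix(runif(30 * 6, 0.01, 1), 30), 5, 6,
                      wl = seq_len(6))
  thresholds <- sort(runif(6, 0.01, 1.2))
  prev <- samSelect(cube, c(2, 3), thresholds[1])
  for (th in thresholds[-1]) {
    cur <- samSelect(cube, c(2, 3), th)
    expect_true(all(cur[prev]))  # nesting
    prev <- cur
  }
})

test_that("a half-gap threshold separates phantom classes (brute-force SAM)", {
  spec <- smallPhantomSpec(jitter_sd = 0.005, noise_sd = 5,
                           specular_fraction = 0)
  scene <- generateScene(spec, seed = 21)
  cube <- calibrate(scene$raw, scene$refs)$cube
  truth <- labelMatrix(scene$truth)
  em <- scene$endmembers
  gap <- min(utils::combn(4, 2, function(p) samAngle(em[p[1], ], em[p[2], ])))

  ref <- which(truth == classCodes()[["tumor"]], arr.ind = TRUE)[1, ]
  mask <- samSelect(cube, ref, gap / 2)

  # independent brute-force SAM over every pixel
  mat <- matrix(cubeData(cube), spec@rows * spec@cols, spec@bands)
  refspec <- cubeData(cube)[ref[1], ref[2], ]
  brute <- vapply(seq_len(nrow(mat)), function(i) {
    if (all(mat[i, ] == 0)) return(FALSE)
    samAngle(mat[i, ], refspec) <= gap / 2
  }, logical(1))
  brute[(ref[2] - 1) * spec@rows + ref[1]] <- TRUE
  expect_identical(as.vector(mask), brute)

  # selected labeled pixels are tumor-only
  sel_lab <- truth[mask & truth != 0]
  expect_true(all(sel_lab == classCodes()[["tumor"]]))
})

test_that("assignClass respects existing labels unless overwriting", {
  map <- GoldStandardMap(dim = c(4, 4))
  empty <- matrix(FALSE, 4, 4)
  expect_identical(labelMatrix(assignClass(map, empty, 1)), labelMatrix(map))

  m1 <- matrix(FALSE, 4, 4); m1[1:2, 1] <- TRUE
  m2 <- matrix(FALSE, 4, 4); m2[3:4, 4] <- TRUE
  map <- assignClass(map, m1, classCodes()[["tumor"]], note = "ref=(1,1)")
  map <- assignClass(map, m2, classCodes()[["normal"]])
  expect_equal(sum(labelMatrix(map) == classCodes()[["tumor"]]), 2)
  expect_equal(sum(labelMatrix(map) == classCodes()[["normal"]]), 2)
  expect_identical(map@provenance, "ref=(1,1)")

  overlap <- matrix(FALSE, 4, 4); overlap[2, 1] <- TRUE
  expect_error(assignClass(map, overlap, classCodes()[["vessel"]]),
               "overwrite")
  ok <- assignClass(map, overlap, classCodes()[["vessel"]], overwrite = TRUE)
  expect_equal(labelMatrix(ok)[2, 1], classCodes()[["vessel"]])

  expect_error(assignClass(map, matrix(FALSE, 2, 2), 1), "shape")
  expect_error(assignClass(map, empty, 0), "1..4")
})

test_that("assembleDataset keeps one row per labeled pixel with its subject", {
  cube1 <- tinyCube(5, 5, 3, wl = c(1, 2, 3), values = runif(75))
  cube2 <- tinyCube(4, 6, 3, wl = c(1, 2, 3), values = runif(72))
  lab1 <- matrix(0L, 5, 5); lab1[1:10] <- 1L
  lab2 <- matrix(0L, 4, 6); lab2[1:15] <- 2L
  ds <- assembleDataset(list(
    list(cube = cube1, map = GoldStandardMap(labels = lab1), subject = "a"),
    list(cube = cube2, map = GoldStandardMap(labels = lab2), subject = "b",
         subtype = "GBM")
  ))
  expect_equal(nSignatures(ds), 25)
  expect_equal(unname(classCounts(ds)[c("normal", "tumor")]), c(10L, 15L))
  expect_identical(unique(ds@groups), c("a", "b"))
  expect_identical(unique(ds@subtype[ds@labels == 2L]), "GBM")

  empty_map <- GoldStandardMap(dim = c(5, 5))
  expect_error(
    assembleDataset(list(list(cube = cube1, map = empty_map, subject = "a"))),
    "no labeled"
  )
})

test_that("datasetSummary reproduces campaign bookkeeping and conserves N", {
  # class/subtype composition of a 22-patient 36-capture campaign
  counts <- c(normal = 117242, vessel = 57429, background = 186118)
  tumor <- c(GBM = 12641, `Anaplastic Oligodendroglioma` = 1844,
             Lung = 1936, Renal = 21, Breast = 325)
  labels <- c(
    rep(classCodes()[["normal"]], counts["normal"]),
    rep(classCodes()[["tumor"]], sum(tumor)),
    rep(classCodes()[["vessel"]], counts["vessel"]),
    rep(classCodes()[["background"]], counts["background"])
  )
  subtype <- rep("", length(labels))
  subtype[labels == classCodes()[["tumor"]]] <- rep(names(tumor), tumor)
  ds <- TrainingDataset(matrix(0, length(labels), 2), labels,
                        groups = "campaign", subtype = subtype)
  summ <- datasetSummary(ds)
  expect_equal(summ$pixels[summ$class == "total"], 377556)
  expect_equal(sum(summ$pixels[summ$class != "total"]), 377556)
  expect_setequal(summ$subtype[summ$class == "tumor"], names(tumor))
  expect_equal(summ$pixels[summ$subtype == "GBM"], 12641)

  # conservation holds for arbitrary small datasets, with or without
  # subtype annotation
  set.seed(2)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    ds2 <- TrainingDataset(matrix(rnorm(2 * n), n),
                           sample(1:4, n, replace = TRUE))
    s2 <- datasetSummary(ds2)
    expect_equal(s2$pixels[s2$class == "total"], n)
  }

  solo <- TrainingDataset(matrix(0, 7, 2), rep(3L, 7))
  s3 <- datasetSummary(solo)
  expect_equal(s3$pixels[s3$class == "total"],
               s3$pixels[s3$class == "vessel"])
})
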