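test_that("ENVI round trip is bit-identical across dtypes and interleaves", {
  float_cube <- tinyCube(3, 4, 5, values = runif(60) * 100,
                         units = "reflectance_percent")
  int_cube <- tinyCube(3, 4, 5, values = sample(0:255, 60, replace = TRUE))
  cases <- expand.grid(
    interleave = c("bsq", "bil", "bip"),
    dtype = c("float64", "float32", "uint16", "uint8"),
    byte_order = c(0L, 1L),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    cube <- if (cases$dtype[i] %in% c("float64", "float32")) {
      if (cases$dtype[i] == "float32") {
        # values exactly representable in binary32
        tinyCube(3, 4, 5, values = sample(0:4095, 60) / 4,
                 units = "reflectance_percent")
      } else {
        float_cube
      }
    } else {
      int_cube
    }
    hdr <- tempfile(fileext = ".hdr")
    writeEnviCube(cube, hdr, interleave = cases$interleave[i],
                  dtype = cases$dtype[i], byte_order = cases$byte_order[i])
    back <- readEnviCube(hdr)
    expect_identical(cubeData(back), cubeData(cube),
                     label = paste(unlist(cases[i, ]), collapse = "/"))
    expect_identical(wavelengths(back), wavelengths(cube))
    expect_identical(cubeUnits(back), cubeUnits(cube))
    file.remove(hdr, sub("\\.hdr$", "", hdr))
  }
})

test_that("reader recovers bytes written by an independent script", {
  # 2 x 2 x 3 bsq little-endian float32 raster written with raw writeBin
  # calls (no package code), band-major with samples fastest
  vals <- c(
    1.5, 2.5, 3.5, 4.5,     # band 1: (r1c1, r1c2, r2c1, r2c2)
    10, 20, 30, 40,         # band 2
    -1, 0, 0.25, 100        # band 3
  )
  bin <- tempfile()
  con <- file(bin, "wb")
  writeBin(vals, con, size = 4L, endian = "little")
  close(con)
  writeLines(c(
    "ENVI",
    "samples = 2", "lines = 2", "bands = 3",
    "header offset = 0", "data type = 4", "interleave = bsq",
    "byte order = 0",
    "wavelength = {500.0, 600.0, 700.0}"
  ), paste0(bin, ".hdr"))
  cube <- readEnviCube(paste0(bin, ".hdr"))
  expect_equal(cubeDim(cube), c(2L, 2L, 3L))
  # bsq order: within a band, samples (cols) vary fastest, then lines
  expect_equal(cubeData(cube)[1, 1, ], c(1.5, 10, -1))
  expect_equal(cubeData(cube)[1, 2, ], c(2.5, 20, 0))
  expect_equal(cubeData(cube)[2, 1, ], c(3.5, 30, 0.25))
  expect_equal(cubeData(cube)[2, 2, ], c(4.5, 40, 100))
  expect_equal(wavelengths(cube), c(500, 600, 700))
})

test_that("malformed headers and cubes are rejected with clear errors", {
  cube <- tinyCube()
  hdr <- tempfile(fileext = ".hdr")
  writeEnviCube(cube, hdr)

  # wavelength list removed -> error naming the key
  lines <- readLines(hdr)
  writeLines(lines[!grepl("^wavelength =", lines)], hdr)
  expect_error(readEnviCube(hdr), "wavelength")

  # wavelength count inconsistent with band count
  writeLines(c(lines[!grepl("^wavelength =", lines)],
               "wavelength = {450, 600, 750}"), hdr)
  expect_error(readEnviCube(hdr), "3 wavelengths for 4 bands")

  # dims inconsistent with file size
  writeLines(sub("^lines = 2", "lines = 7", lines), hdr)
  expect_error(readEnviCube(hdr), "inconsistent")

  # cubes with zero rows cannot even be constructed
  expect_error(HyperCube(array(0, c(0, 2, 3)), c(1, 2, 3)), "rows")
  # wavelength axis shorter than the band count is an invariant violation
  expect_error(HyperCube(array(0, c(2, 2, 3)), c(1, 2)), "wavelength")
})

test_that("bandIndex finds nearest band with lower-index tie-break", {
  cube <- HyperCube(array(1, c(1, 1, 3)), c(479.06, 539.44, 708.97))
  expect_identical(bandIndex(cube, 539.44), 2L)  # green band, exact hit
  expect_identical(bandIndex(cube, 479.06), 1L)
  # equidistant between two bands resolves to the lower index
  even <- HyperCube(array(1, c(1, 1, 5)), c(10, 20, 30, 40, 50))
  expect_identical(bandIndex(even, 35), 3L)
  expect_error(bandIndex(cube, 2000), "outside")
  expect_error(bandIndex(cube, 100), "outside")
})

test_that("bandIndex is stable under sub-half-gap wavelength perturbation", {
  wl <- sort(runif(20, 400, 1000))
  wl <- wl[c(TRUE, diff(wl) > 1)]
  cube <- HyperCube(array(1, c(1, 1, length(wl))), wl)
  gaps <- diff(wl)
  for (i in seq_along(wl)) {
    half <- min(gaps[max(1, i - 1)], gaps[min(length(gaps), i)]) / 2
    for (eps in c(-0.49, 0.49) * half) {
      expect_identical(bandIndex(cube, wl[i] + eps), i)
    }
  }
})

test_that("syntheticRGB selects the VNIR triplet and rescales channels", {
  wl <- vnirWavelengths(bands = 40)
  arr <- array(runif(6 * 5 * 40), c(6, 5, 40))
  cube <- HyperCube(arr, wl)
  rgb <- syntheticRGB(cube)
  expect_equal(dim(rgb), c(6, 5, 3))
  expect_true(all(rgb >= 0 & rgb <= 1))
  # each channel independently spans [0, 1] after min-max rescaling
  for (k in 1:3) expect_equal(range(rgb[, , k]), c(0, 1))

  # bands already in [0, 1] and spanning it pass through unchanged
  arr2 <- array(0.5, c(2, 2, 3))
  arr2[, , 1] <- matrix(c(0, 1, 0.25, 0.75), 2)
  arr2[, , 2] <- matrix(c(1, 0, 0.5, 0.5), 2)
  arr2[, , 3] <- 0.4  # constant band -> zero channel
  cube2 <- HyperCube(arr2, c(479.06, 539.44, 708.97))
  rgb2 <- syntheticRGB(cube2)
  expect_equal(rgb2[, , 1], arr2[, , 3] * 0)    # constant red band
  expect_equal(rgb2[, , 2], arr2[, , 2])
  expect_equal(rgb2[, , 3], arr2[, , 1])
})

test_that("spatialExtentMm reproduces the acquisition geometry arithmetic", {
  expect_identical(spatialExtentMm(1787, 128.7), 230L)
  expect_identical(spatialExtentMm(1004, 128.7), 129L)
  expect_identical(spatialExtentMm(1, 1000), 1L)
  expect_error(spatialExtentMm(0, 128.7))
  expect_error(spatialExtentMm(100, -1))
  # monotone non-decreasing in both arguments
  px <- sort(sample(1:3000, 10))
  expect_true(all(diff(vapply(px, spatialExtentMm,
                              integer(1), pixel_pitch_um = 128.7)) >= 0))
  pitch <- sort(runif(10, 50, 500))
  expect_true(all(diff(vapply(pitch, function(p) spatialExtentMm(1000, p),
                              integer(1))) >= 0))
})

test_that("label maps round-trip through the ENVI classification raster", {
  labels <- matrix(sample(0:4, 30, replace = TRUE), 5, 6)
  map <- GoldStandardMap(labels = labels)
  hdr <- tempfile(fileext = ".hdr")
  writeLabelMap(map, hdr)
  back <- readLabelMap(hdr)
  expect_identical(labelMatrix(back), labels)
})
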