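## ENVI-dialect cube input/output and acquisition-geometry helpers.
##
## ENVI (header text file + headerless binary raster) is the de-facto
## interchange dialect for pushbroom hyperspectral cameras; no installed R
## package reads it, so the parser/writer live here. Storage orders bsq,
## bil and bip are supported with little/big endian and the common data
## types (uint8, int16, int32, float32, float64, uint16).

.ENVI_DTYPES <- data.frame(
  code = c(1L, 2L, 3L, 4L, 5L, 12L),
  what = c("integer", "integer", "integer", "double", "double", "integer"),
  size = c(1L, 2L, 4L, 4L, 8L, 2L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
  name = c("uint8", "int16", "int32", "float32", "float64", "uint16")
)

.dtypeRow <- function(code) {
  i <- match(code, .ENVI_DTYPES$code)
  if (is.na(i)) stop("unsupported ENVI data type code: ", code)
  .ENVI_DTYPES[i, ]
}

# Parse an ENVI header into a named list; `{ ... }` values become numeric
# or character vectors.
.parseEnviHeader <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  if (!length(lines) || !grepl("^ENVI", lines[[1]])) {
    stop("not an ENVI header (missing 'ENVI' magic line): ", header_path)
  }
  txt <- paste(lines[-1], collapse = "\n")
  out <- list()
  # join multi-line { } blocks, then split on key = value
  pos <- 1L
  while (pos <= nchar(txt)) {
    rest <- substring(txt, pos)
    m <- regexpr("^\\s*([^=\n]+?)[ \t]*=[ \t]*", rest, perl = TRUE)
    if (m == -1L) break
    matched <- regmatches(rest, m)
    key <- tolower(gsub("\\s+", " ", trimws(sub("\\s*=\\s*$", "", matched))))
    pos <- pos + attr(m, "match.length")
    rest <- substring(txt, pos)
    if (substring(rest, 1, 1) == "{") {
      close <- regexpr("}", rest, fixed = TRUE)
      if (close == -1L) stop("unterminated '{' in header for key '", key, "'")
      val <- substring(rest, 2, close - 1L)
      pos <- pos + close
      items <- trimws(strsplit(val, ",")[[1]])
      items <- items[nzchar(items)]
      num <- suppressWarnings(as.numeric(items))
      out[[key]] <- if (length(items) && !anyNA(num)) num else items
    } else {
      eol <- regexpr("\n", rest, fixed = TRUE)
      if (eol == -1L) eol <- nchar(rest) + 1L
      out[[key]] <- trimws(substring(rest, 1, eol - 1L))
      pos <- pos + eol
    }
  }
  out
}

#' Read a hyperspectral cube in ENVI format
#'
#' Reads an ENVI header/raster pair into a [HyperCube-class]. The header
#' must name `samples`, `lines`, `bands`, `data type`, `interleave` and a
#' `wavelength` list; `byte order` is honored. The binary file is the
#' header path without its `.hdr` extension (or as given by the header's
#' sibling file).
#'
#' @param header_path path to the `.hdr` text header.
#' @return A [HyperCube-class] with populated wavelength axis; the `units`
#'   flag is restored from the `data units` header key when present.
#' @seealso [writeEnviCube()]
#' @export
readEnviCube <- function(header_path) {
  h <- .parseEnviHeader(header_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    stop("ENVI header is missing required key(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(h[["wavelength"]])) {
    stop("ENVI header has no 'wavelength' list; a wavelength axis is required")
  }
  cols <- as.integer(h[["samples"]])
  rows <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  wl <- as.numeric(h[["wavelength"]])
  if (length(wl) != bands) {
    stop(sprintf(
      "header lists %d wavelengths for %d bands", length(wl), bands
    ))
  }
  interleave <- tolower(h[["interleave"]])
  dt <- .dtypeRow(as.integer(h[["data type"]]))
  endian <- if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) == 1L) {
    "big"
  } else {
    "little"
  }
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  bin_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(bin_path)) {
    stop("raster file not found next to header: ", bin_path)
  }
  n <- rows * cols * bands
  expect_bytes <- offset + as.numeric(n) * dt$size
  if (file.size(bin_path) != expect_bytes) {
    stop(sprintf(
      "raster size (%d bytes) inconsistent with header dims (%d x %d x %d, %s): expected %d bytes",
      file.size(bin_path), rows, cols, bands, dt$name, expect_bytes
    ))
  }
  con <- file(bin_path, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", n = offset)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  arr <- switch(interleave,
    bsq = aperm(array(v, c(cols, rows, bands)), c(2, 1, 3)),
    bil = aperm(array(v, c(cols, bands, rows)), c(3, 1, 2)),
    bip = aperm(array(v, c(bands, cols, rows)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave)
  )
  units <- if (!is.null(h[["data units"]])) h[["data units"]] else "raw"
  nm <- if (!is.null(h[["cube name"]])) h[["cube name"]] else ""
  HyperCube(arr * 1.0, wl, units = units, name = nm)
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<path without .hdr>` (binary raster) plus the `.hdr` text
#' header. Default storage is band-sequential float64 little-endian, which
#' round-trips [readEnviCube()] bit-identically; integer types truncate
#' non-integral values.
#'
#' @param cube a [HyperCube-class].
#' @param header_path output `.hdr` path (binary raster written alongside).
#' @param interleave `"bsq"` (default), `"bil"` or `"bip"`.
#' @param dtype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`, `"uint16"`.
#' @param byte_order 0 little-endian (default) or 1 big-endian.
#' @return Invisibly, the header path.
#' @export
writeEnviCube <- function(cube, header_path, interleave = c("bsq", "bil", "bip"),
                          dtype = "float64", byte_order = 0L) {
  stopifnot(is(cube, "HyperCube"))
  validObject(cube)
  interleave <- match.arg(interleave)
  dt <- .ENVI_DTYPES[match(dtype, .ENVI_DTYPES$name), ]
  if (anyNA(dt)) stop("unsupported dtype: ", dtype)
  d <- dim(cube@data)
  arr <- cube@data
  v <- switch(interleave,
    bsq = as.vector(aperm(arr, c(2, 1, 3))),
    bil = as.vector(aperm(arr, c(2, 3, 1))),
    bip = as.vector(aperm(arr, c(3, 2, 1)))
  )
  endian <- if (byte_order == 1L) "big" else "little"
  bin_path <- sub("\\.hdr$", "", header_path)
  con <- tryCatch(file(bin_path, "wb"), error = function(e) {
    stop("cannot write raster file: ", bin_path)
  })
  if (dt$what == "integer") v <- as.integer(v)
  writeBin(v, con, size = dt$size, endian = endian)
  close(con)
  hdr <- c(
    "ENVI",
    "description = {hsbrain ENVI export}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dt$code),
    sprintf("interleave = %s", interleave),
    sprintf("byte order = %d", byte_order),
    "wavelength units = Nanometers",
    sprintf("data units = %s", cube@units),
    sprintf("cube name = %s", cube@name),
    sprintf("wavelength = {%s}",
            paste(sprintf("%.17g", cube@wavelengths), collapse = ", "))
  )
  writeLines(hdr, header_path)
  invisible(header_path)
}

#' Write / read a label raster in ENVI format
#'
#' Gold-standard label maps are stored as single-band uint8 ENVI rasters
#' with the class palette of [classCodes()] recorded in the header.
#'
#' @param map a [GoldStandardMap-class].
#' @param header_path `.hdr` path.
#' @return `writeLabelMap` invisibly returns the header path;
#'   `readLabelMap` returns a [GoldStandardMap-class].
#' @export
writeLabelMap <- function(map, header_path) {
  stopifnot(is(map, "GoldStandardMap"))
  d <- dim(map@labels)
  bin_path <- sub("\\.hdr$", "", header_path)
  con <- file(bin_path, "wb")
  writeBin(as.integer(t(map@labels)), con, size = 1L)
  close(con)
  hdr <- c(
    "ENVI",
    "description = {hsbrain label raster; 0 unlabeled, 1 normal, 2 tumor, 3 vessel, 4 background}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    "bands = 1",
    "header offset = 0",
    "file type = ENVI Classification",
    "data type = 1",
    "interleave = bsq",
    "byte order = 0"
  )
  writeLines(hdr, header_path)
  invisible(header_path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(header_path) {
  h <- .parseEnviHeader(header_path)
  cols <- as.integer(h[["samples"]])
  rows <- as.integer(h[["lines"]])
  bin_path <- sub("\\.hdr$", "", header_path)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = rows * cols, size = 1L, signed = FALSE)
  GoldStandardMap(labels = matrix(v, rows, cols, byrow = TRUE))
}

#' Locate the band nearest a target wavelength
#'
#' @param cube a [HyperCube-class].
#' @param target_nm target wavelength (nm). Must lie within the cube's
#'   wavelength range extended by half the local inter-band spacing at each
#'   end.
#' @return 1-based band index minimizing `|wavelength - target|`; exact
#'   ties resolve to the lower index.
#' @export
#' @examples
#' cube <- HyperCube(array(1, c(1, 1, 3)), c(479.06, 539.44, 708.97))
#' bandIndex(cube, 539.44)  # 2
bandIndex <- function(cube, target_nm) {
  wl <- cube@wavelengths
  n <- length(wl)
  lo <- wl[1] - (wl[2] - wl[1]) / 2
  hi <- wl[n] + (wl[n] - wl[n - 1]) / 2
  if (target_nm < lo || target_nm > hi) {
    stop(sprintf(
      "target %.2f nm outside cube range [%.2f, %.2f] nm", target_nm, wl[1], wl[n]
    ))
  }
  which.min(abs(wl - target_nm))
}

#' Synthetic RGB rendering of a cube
#'
#' Selects the bands nearest three target wavelengths and min-max rescales
#' each channel to `[0, 1]` independently (a constant channel renders as
#' zeros). The default triplet reproduces the VNIR camera-software
#' convention: red 708.97 nm, green 539.44 nm, blue 479.06 nm.
#'
#' @param cube a [HyperCube-class].
#' @param nm_triplet numeric length 3, `c(red, green, blue)` wavelengths
#'   in nm.
#' @return rows x cols x 3 numeric array in `[0, 1]`.
#' @export
syntheticRGB <- function(cube, nm_triplet = c(708.97, 539.44, 479.06)) {
  stopifnot(length(nm_triplet) == 3L)
  d <- dim(cube@data)
  out <- array(0, c(d[1], d[2], 3L))
  for (c_i in 1:3) {
    b <- bandIndex(cube, nm_triplet[c_i])
    ch <- cube@data[, , b]
    rng <- range(ch)
    if (rng[2] > rng[1]) {
      out[, , c_i] <- (ch - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Spatial extent of a scan axis in millimetres
#'
#' Converts a pixel count and pixel pitch to the printed scene extent,
#' rounding half-up to the nearest millimetre: e.g. 1787 pixels at
#' 128.7 um/pixel span 230 mm, and 1004 pixels span 129 mm.
#'
#' @param n_pixels number of pixels along the axis (>= 1).
#' @param pixel_pitch_um pixel pitch in micrometres (> 0).
#' @return Integer millimetres.
#' @export
#' @examples
#' spatialExtentMm(1787, 128.7)  # 230
#' spatialExtentMm(1004, 128.7)  # 129
spatialExtentMm <- function(n_pixels, pixel_pitch_um) {
  if (n_pixels < 1 || pixel_pitch_um <= 0) {
    stop("n_pixels must be >= 1 and pixel_pitch_um > 0")
  }
  as.integer(floor(n_pixels * pixel_pitch_um / 1000 + 0.5))
}

#' Default VNIR wavelength axis
#'
#' The 826-band visible/near-infrared axis spanning 400-1000 nm
#' (~0.73 nm dispersion per band).
#'
#' @param bands number of bands (default 826).
#' @param range_nm wavelength range (default `c(400, 1000)`).
#' @return Numeric vector of band-centre wavelengths.
#' @export
vnirWavelengths <- function(bands = 826L, range_nm = c(400, 1000)) {
  seq(range_nm[1], range_nm[2], length.out = bands)
}

#' Export an RGB array or TMD map as PNG
#'
#' @param x rows x cols x 3 array in `[0, 1]`, or a [TMDMap-class].
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
writeRGBPng <- function(x, path) {
  if (is(x, "TMDMap")) x <- x@rgb
  png::writePNG(x, path)
  invisible(path)
}
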