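# shared fixtures: tiny deterministic cubes and small phantom specs

tinyCube <- function(rows = 2, cols = 3, bands = 4,
                     wl = seq(450, 900, length.out = bands),
                     values = NULL, units = "raw") {
  if (is.null(values)) values <- seq_len(rows * cols * bands)
  HyperCube(array(as.numeric(values), c(rows, cols, bands)), wl,
            units = units)
}

# spectrum-per-pixel cube: spectra is n_px x bands, pixels fill the grid
# column-major
spectraCube <- function(spectra, rows, cols,
                        wl = seq(450, 900, length.out = ncol(spectra)),
                        units = "reflectance_percent") {
  HyperCube(array(spectra, c(rows, cols, ncol(spectra))), wl, units = units)
}

# small phantom used by module tests (fast; full-size scenes are exercised
# in the end-to-end acceptance suite)
smallPhantomSpec <- function(...) {
  phantomSpec(rows = 32, cols = 32, bands = 48, ...)
}

smallChain <- function(...) {
  preprocessConfig(target_bands = 24, ...)
}

# reference flat probability map
uniformProbMap <- function(rows, cols, nclass = 4) {
  ProbabilityMap(array(1 / nclass, c(rows, cols, nclass)),
                 classOrder = seq_len(nclass))
}
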