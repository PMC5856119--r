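#' @include preprocess.R
NULL

## End-to-end in-situ pipeline: calibrate -> preprocess -> {PCA + SVM +
## k-NN || HKM} -> majority voting -> TMD map, with per-stage wall times.
## The supervised and unsupervised branches form independent arms of the
## stage graph, joined at the majority-voting fusion.

#' PipelineConfig: settings of the end-to-end run
#'
#' @slot preprocess a [PreprocessConfig-class].
#' @slot K number of segmentation clusters.
#' @slot knnK,lambda k-NN filter neighbors and spatial weight.
#' @slot colors class-color matrix for the TMD rendering.
#' @slot seed seed used by the clustering stage.
#' @slot soft use soft-probability cluster densities instead of hard
#'   argmax counts.
#'
#' @aliases PipelineConfig-class
#' @export
setClass("PipelineConfig",
  representation(
    preprocess = "PreprocessConfig", K = "integer", knnK = "integer",
    lambda = "numeric", colors = "matrix", seed = "integer",
    soft = "logical"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@K < 1L) return("K must be >= 1")
  if (object@knnK < 1L) return("knnK must be >= 1")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' Construct a PipelineConfig
#'
#' @param preprocess a [PreprocessConfig-class].
#' @param K segmentation cluster count (default 24).
#' @param knn_k k-NN filter neighborhood size (default 40).
#' @param lambda k-NN spatial weight (default 1).
#' @param colors class-color matrix (default [classColors()]).
#' @param seed clustering seed (default 7).
#' @param soft soft-probability densities (default `FALSE`).
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(preprocess = preprocessConfig(), K = 24L,
                           knn_k = 40L, lambda = 1, colors = classColors(),
                           seed = 7L, soft = FALSE) {
  new("PipelineConfig",
    preprocess = preprocess, K = as.integer(K), knnK = as.integer(knn_k),
    lambda = lambda, colors = colors, seed = as.integer(seed), soft = soft
  )
}

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(
    "PipelineConfig: K = %d clusters, knn K = %d, lambda = %g, seed = %d\n",
    object@K, object@knnK, object@lambda, object@seed
  ))
})

#' Read a pipeline configuration from YAML
#'
#' Schema (all keys optional, unknown keys rejected): `preprocess`
#' (`keep_range`, `smooth_window`, `smooth_kind`, `target_bands`,
#' `normalize`), `K`, `knn_k`, `lambda`, `seed`, `soft`, `background_color`
#' (`"black"`/`"white"`).
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("preprocess", "K", "knn_k", "lambda", "seed", "soft",
             "background_color")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  pp_args <- y$preprocess
  if (!is.null(pp_args)) {
    pp_known <- c("keep_range", "smooth_window", "smooth_kind",
                  "target_bands", "normalize")
    bad <- setdiff(names(pp_args), pp_known)
    if (length(bad)) {
      stop("unknown preprocess key(s): ", paste(bad, collapse = ", "))
    }
    if (!is.null(pp_args$keep_range)) {
      pp_args$keep_range <- as.numeric(unlist(pp_args$keep_range))
    }
  }
  pp <- do.call(preprocessConfig, if (is.null(pp_args)) list() else pp_args)
  args <- y[setdiff(names(y), c("preprocess", "background_color"))]
  names(args)[names(args) == "knn_k"] <- "knn_k"
  colors <- classColors(
    if (is.null(y$background_color)) "black" else y$background_color
  )
  do.call(pipelineConfig, c(list(preprocess = pp, colors = colors), args))
}

#' Run the full delineation pipeline on one acquisition
#'
#' Executes the in-situ stage graph on a raw cube: reflectance calibration,
#' the spectral homogenization chain, the spatial-spectral supervised arm
#' (first principal component, SVM probabilities, k-NN filtering) and the
#' unsupervised arm (bisecting hierarchical K-means), joined by
#' per-cluster majority voting and rendered as the three-maximum-density
#' map. Any stage failure aborts with the stage name; per-stage wall times
#' are returned.
#'
#' @param raw a raw [HyperCube-class].
#' @param refs a [ReferenceFrames-class].
#' @param model a trained [ClassifierModel-class] (same preprocessing
#'   chain as `config@preprocess`).
#' @param config a [PipelineConfig-class].
#' @return A list: `tmd` ([TMDMap-class]), `votes` (per-cluster class
#'   codes), `voteMap` (pixel class-code matrix), `densities`
#'   ([ClusterDensities-class]), `segmentation` ([SegmentationMap-class]),
#'   `probabilities` and `filtered` ([ProbabilityMap-class]), `guide`
#'   (PC1 matrix), `calibrated` (result of [calibrate()]), `preprocessed`
#'   ([HyperCube-class]) and `timing` (data frame with stages
#'   `pre_processing`, `pca_svm`, `knn`, `hkm`, `mv`, plus `calibration`
#'   and `tmd`).
#' @export
runPipeline <- function(raw, refs, model, config = pipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  timing <- data.frame(stage = character(), seconds = numeric())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timing[nrow(timing) + 1L, ] <<- list(name, proc.time()[["elapsed"]] - t0)
    val
  }
  cal <- stage("calibration", calibrate(raw, refs))
  pp <- stage("pre_processing", preprocess(cal$cube, config@preprocess))
  sup <- stage("pca_svm", {
    list(guide = pcaFirstComponent(pp),
         probs = predictProbabilities(model, pp))
  })
  filtered <- stage("knn", knnFilter(sup$probs, sup$guide,
                                     K = config@knnK,
                                     lambda = config@lambda))
  seg <- stage("hkm", hierarchicalKmeans(pp, K = config@K,
                                         seed = config@seed))
  fused <- stage("mv", {
    dens <- classDensities(seg, filtered, soft = config@soft)
    list(densities = dens, votes = majorityVote(dens))
  })
  tmd <- stage("tmd", renderTMD(seg, fused$densities, config@colors))
  list(
    tmd = tmd, votes = fused$votes,
    voteMap = voteMap(seg, fused$votes),
    densities = fused$densities, segmentation = seg,
    probabilities = sup$probs, filtered = filtered, guide = sup$guide,
    calibrated = cal, preprocessed = pp, timing = timing
  )
}

#' Write the per-cluster density/vote sidecar
#'
#' JSON sidecar accompanying a TMD raster: per-cluster sizes, class
#' densities and majority votes.
#'
#' @param result a [runPipeline()] result.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
writeTMDSidecar <- function(result, path) {
  dens <- densityMatrix(result$densities)
  codes <- .tissueCodes()
  payload <- list(
    classes = names(codes)[match(result$densities@classOrder, codes)],
    cluster_sizes = as.integer(clusterSizes(result$segmentation)),
    densities = unname(apply(dens, 1, as.numeric, simplify = FALSE)),
    votes = names(codes)[match(result$votes, codes)],
    timing = result$timing
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
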