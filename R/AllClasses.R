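#' @import methods
NULL

.CLASS_LEVELS <- c("Tumor", "NonNeoplastic", "Ignore")
.TRUTH_LEVELS <- c("Tumor", "NonNeoplastic", "Artifact")

#' Parametrization of a synthetic H&E field
#'
#' A `SceneSpec` fixes everything about a simulated tile: its pixel
#' dimensions, the scan resolution in microns per pixel, how many tumor
#' nuclei, non-neoplastic nuclei and non-nuclear artifact objects to place,
#' the class-wise mean nuclear areas (tumor nuclei are larger than the
#' surrounding non-neoplastic cells), the allowed pairwise overlap, the ROI
#' inset and the random seed. A given spec reproduces its scene
#' bit-identically.
#'
#' @slot widthPx,heightPx tile size in pixels.
#' @slot mpp microns per pixel (default 0.4416, a 20x scan).
#' @slot nTumor,nNonneo,nArtifact object counts per class.
#' @slot tumorMeanAreaUm2,nonneoMeanAreaUm2 mean nuclear areas in square
#'   microns; the tumor mean must exceed the non-neoplastic mean.
#' @slot areaCV coefficient of variation of nuclear area within a class.
#' @slot maxOverlapFrac maximum allowed pairwise overlap area as a fraction
#'   of the smaller object, in `[0, 1)`.
#' @slot roiMarginPx inset of the rectangular ROI from the tile border.
#' @slot seed integer random seed.
#' @seealso [sceneSpec()], [generateScene()]
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  widthPx = "integer", heightPx = "integer", mpp = "numeric",
  nTumor = "integer", nNonneo = "integer", nArtifact = "integer",
  tumorMeanAreaUm2 = "numeric", nonneoMeanAreaUm2 = "numeric",
  areaCV = "numeric", maxOverlapFrac = "numeric",
  roiMarginPx = "integer", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@widthPx < 64L || object@heightPx < 64L)
    msg <- c(msg, "tile must be at least 64 x 64 px")
  if (object@mpp <= 0) msg <- c(msg, "mpp must be > 0")
  if (any(c(object@nTumor, object@nNonneo, object@nArtifact) < 0L))
    msg <- c(msg, "object counts must be >= 0")
  if (object@tumorMeanAreaUm2 <= object@nonneoMeanAreaUm2)
    msg <- c(msg, "tumorMeanAreaUm2 must exceed nonneoMeanAreaUm2")
  if (object@nonneoMeanAreaUm2 <= 0) msg <- c(msg, "mean areas must be > 0")
  if (object@areaCV < 0) msg <- c(msg, "areaCV must be >= 0")
  if (object@maxOverlapFrac < 0 || object@maxOverlapFrac >= 1)
    msg <- c(msg, "maxOverlapFrac must be in [0, 1)")
  if (object@roiMarginPx < 0 ||
      2L * object@roiMarginPx >= min(object@widthPx, object@heightPx))
    msg <- c(msg, "roiMarginPx leaves no ROI interior")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' @param widthPx,heightPx tile size in pixels (default 1024).
#' @param mpp microns per pixel; the default 0.4416 corresponds to a 20x scan.
#' @param nTumor,nNonneo,nArtifact counts of tumor nuclei, non-neoplastic
#'   nuclei and non-nuclear artifact objects.
#' @param tumorMeanAreaUm2,nonneoMeanAreaUm2 mean nuclear area per class in
#'   square microns. Tumor nuclei must be larger on average.
#' @param areaCV within-class coefficient of variation of nuclear area.
#' @param maxOverlapFrac maximum pairwise overlap area as a fraction of the
#'   smaller object (0 = strictly disjoint).
#' @param roiMarginPx inset of the rectangular ROI from the tile border.
#' @param seed integer seed; the scene is a pure function of the spec.
#' @return a validated [SceneSpec-class] object.
#' @examples
#' spec <- sceneSpec(nTumor = 30, nNonneo = 70, nArtifact = 10, seed = 1)
#' @export
sceneSpec <- function(widthPx = 1024L, heightPx = 1024L, mpp = 0.4416,
                      nTumor = 30L, nNonneo = 70L, nArtifact = 10L,
                      tumorMeanAreaUm2 = 80, nonneoMeanAreaUm2 = 25,
                      areaCV = 0.25, maxOverlapFrac = 0,
                      roiMarginPx = 32L, seed = 1L) {
  new("SceneSpec",
      widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      mpp = as.numeric(mpp),
      nTumor = as.integer(nTumor), nNonneo = as.integer(nNonneo),
      nArtifact = as.integer(nArtifact),
      tumorMeanAreaUm2 = as.numeric(tumorMeanAreaUm2),
      nonneoMeanAreaUm2 = as.numeric(nonneoMeanAreaUm2),
      areaCV = as.numeric(areaCV), maxOverlapFrac = as.numeric(maxOverlapFrac),
      roiMarginPx = as.integer(roiMarginPx), seed = as.integer(seed))
}

#' A synthetic H&E scene with per-object ground truth
#'
#' Produced by [generateScene()]. Holds the rendered RGB tile, the ground
#' truth table (one row per placed object with its true class, centroid,
#' ellipse parameters and polygon outline) and the rectangular ROI polygon
#' emulating the pathologist's pen marking.
#'
#' @slot image numeric array `height x width x 3`, values in `[0, 1]`,
#'   quantized to 8-bit levels.
#' @slot cells data.frame with columns `id`, `trueClass`, `x`, `y` (0-based
#'   pixel centroid), `semiMajorPx`, `semiMinorPx`, `thetaRad`, `areaUm2`.
#' @slot polygons list of `n x 2` vertex matrices parallel to `cells`.
#' @slot roi `n x 2` polygon ring of the region of interest.
#' @slot spec the generating [SceneSpec-class].
#' @exportClass HEScene
setClass("HEScene", representation(
  image = "array", cells = "data.frame", polygons = "list",
  roi = "matrix", spec = "SceneSpec"))

setValidity("HEScene", function(object) {
  if (length(object@polygons) != nrow(object@cells))
    return("polygons and cells must be parallel")
  if (nrow(object@cells) &&
      !all(object@cells$trueClass %in% .TRUTH_LEVELS))
    return("unknown trueClass label")
  TRUE
})

#' An observer (pathologist) rating model
#'
#' Emulates a human scorer of tumor cellular fraction on the percent scale:
#' `rating = clip(round(truth + bias + noise))`, rounded to the reporting
#' granularity and clipped to `[0, 100]`. A positive bias reproduces the
#' over-estimation of TCF typical of visual assessment.
#'
#' @slot bias additive mean shift, percent points.
#' @slot noiseSD standard deviation of the rating noise, percent points.
#' @slot rounding reporting granularity (e.g. 5 = nearest 5 percent).
#' @slot seed integer seed.
#' @seealso [observerModel()], [simulateObservers()]
#' @exportClass ObserverModel
setClass("ObserverModel", representation(
  bias = "numeric", noiseSD = "numeric", rounding = "numeric", seed = "integer"))

setValidity("ObserverModel", function(object) {
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (object@rounding <= 0) return("rounding granularity must be > 0")
  TRUE
})

#' Construct an ObserverModel
#' @param bias additive mean shift in percent points (positive =
#'   over-estimation relative to truth).
#' @param noiseSD rating noise SD in percent points.
#' @param rounding reporting granularity in percent (default nearest 5).
#' @param seed integer seed.
#' @return an [ObserverModel-class] object.
#' @export
observerModel <- function(bias = 0, noiseSD = 0, rounding = 5, seed = 1L) {
  new("ObserverModel", bias = as.numeric(bias), noiseSD = as.numeric(noiseSD),
      rounding = as.numeric(rounding), seed = as.integer(seed))
}

#' Nucleus detector parameters
#'
#' @slot odThreshold hematoxylin optical-density cutoff separating nuclear
#'   from background pixels.
#' @slot minAreaUm2,maxAreaUm2 area gates in square microns; detections
#'   outside the gate are discarded.
#' @slot splitMinDistancePx watershed tolerance (in pixels of the distance
#'   transform) used when splitting touching nuclei.
#' @seealso [detectParams()], [detectNuclei()]
#' @exportClass DetectParams
setClass("DetectParams", representation(
  odThreshold = "numeric", minAreaUm2 = "numeric", maxAreaUm2 = "numeric",
  splitMinDistancePx = "numeric"))

setValidity("DetectParams", function(object) {
  if (!(object@minAreaUm2 > 0 && object@minAreaUm2 < object@maxAreaUm2))
    return("need 0 < minAreaUm2 < maxAreaUm2")
  if (object@odThreshold <= 0) return("odThreshold must be > 0")
  TRUE
})

#' Construct DetectParams
#' @param odThreshold hematoxylin OD cutoff (default 0.25).
#' @param minAreaUm2,maxAreaUm2 area gates in square microns (default 8-400,
#'   bracketing lymphocyte through large pleomorphic nuclei).
#' @param splitMinDistancePx watershed tolerance for splitting touching
#'   nuclei (default 3).
#' @return a [DetectParams-class] object.
#' @export
detectParams <- function(odThreshold = 0.25, minAreaUm2 = 8, maxAreaUm2 = 400,
                         splitMinDistancePx = 3) {
  new("DetectParams", odThreshold = as.numeric(odThreshold),
      minAreaUm2 = as.numeric(minAreaUm2), maxAreaUm2 = as.numeric(maxAreaUm2),
      splitMinDistancePx = as.numeric(splitMinDistancePx))
}

#' A set of nucleus detections
#'
#' Container for detections inside an ROI: one row of metadata per detection
#' plus its polygon outline. Produced by [detectNuclei()] or
#' [importDetections()]; labels are filled by [classifyDetections()].
#'
#' @slot data data.frame with columns `id`, `x`, `y` (0-based centroid),
#'   `areaUm2`, `meanOdH`, `meanOdE` and optionally `label`.
#' @slot polygons list of vertex matrices parallel to `data`.
#' @slot mpp microns per pixel used for area conversion.
#' @exportClass DetectionSet
setClass("DetectionSet", representation(
  data = "data.frame", polygons = "list", mpp = "numeric"))

setValidity("DetectionSet", function(object) {
  if (length(object@polygons) != nrow(object@data))
    return("polygons and data must be parallel")
  need <- c("id", "x", "y", "areaUm2")
  if (!all(need %in% names(object@data)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@data) && any(object@data$areaUm2 <= 0))
    return("areaUm2 must be > 0")
  TRUE
})

#' A trained nucleus classifier
#'
#' A randomized decision-tree ensemble over the eight morphometric/intensity
#' features, trained from a small balanced annotation set.
#'
#' @slot model the fitted `randomForest` object.
#' @slot classes character vector of classes seen in training.
#' @slot featureNames feature column names, in training order.
#' @slot trainingCounts named integer vector of annotations per class.
#' @slot seed integer training seed.
#' @exportClass NucleusClassifier
setClass("NucleusClassifier", representation(
  model = "ANY", classes = "character", featureNames = "character",
  trainingCounts = "integer", seed = "integer"))

#' A tumor-cellular-fraction result
#'
#' Counts of classified nuclei inside the ROI, the computational TCF
#' `ctcf = nTumor / (nTumor + nNonneo)` (Ignore-class detections never enter
#' the ratio), and the molecular-adequacy flags.
#'
#' @slot nTumor,nNonneo,nIgnore non-negative counts.
#' @slot ctcf tumor cellular fraction in `[0, 1]`; `NA` when no countable
#'   cells exist (undefined, reported as missing rather than zero).
#' @slot adequateCells `nTumor >= minCells` (default 100).
#' @slot adequateTcf `ctcf >= minTcf` (default 0.20).
#' @slot adequate both conditions hold.
#' @slot minCells,minTcf the thresholds applied.
#' @exportClass TCFResult
setClass("TCFResult", representation(
  nTumor = "integer", nNonneo = "integer", nIgnore = "integer",
  ctcf = "numeric", adequateCells = "logical", adequateTcf = "logical",
  adequate = "logical", minCells = "numeric", minTcf = "numeric"))

setValidity("TCFResult", function(object) {
  if (any(c(object@nTumor, object@nNonneo, object@nIgnore) < 0L))
    return("counts must be >= 0")
  den <- object@nTumor + object@nNonneo
  if (den > 0L) {
    if (!isTRUE(all.equal(object@ctcf, object@nTumor / den)))
      return("ctcf must equal nTumor / (nTumor + nNonneo)")
  } else if (!is.na(object@ctcf)) {
    return("ctcf must be NA when there are no countable cells")
  }
  TRUE
})

#' An ordinal agreement result
#'
#' Quadratic weighted kappa between two raters of binned TCF scores, with a
#' permutation p-value (and the large-sample normal approximation alongside).
#'
#' @slot kappa weighted kappa in `[-1, 1]`; `NA` when expected disagreement
#'   is zero (a constant rater).
#' @slot pValue the p-value of the selected null procedure.
#' @slot pPermutation,pAsymptotic the two p-values individually.
#' @slot n number of rated cases.
#' @slot k number of ordinal categories.
#' @slot method list of metadata: weight scheme, binning, null procedure,
#'   number of permutations, seed, and an explanation when kappa is undefined.
#' @exportClass AgreementResult
setClass("AgreementResult", representation(
  kappa = "numeric", pValue = "numeric", pPermutation = "numeric",
  pAsymptotic = "numeric", n = "integer", k = "integer", method = "list"))

#' @describeIn SceneSpec-class compact display
#' @param object a `SceneSpec`
#' @export
setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px @ %.4f mpp | tumor %d, non-neoplastic %d, artifact %d | seed %d\n",
              object@widthPx, object@heightPx, object@mpp,
              object@nTumor, object@nNonneo, object@nArtifact, object@seed))
})

#' @describeIn HEScene-class compact display
#' @param object an `HEScene`
#' @export
setMethod("show", "HEScene", function(object) {
  tab <- table(factor(object@cells$trueClass, levels = .TRUTH_LEVELS))
  cat(sprintf("HEScene: %d x %d px, %d objects (Tumor %d, NonNeoplastic %d, Artifact %d)\n",
              dim(object@image)[2L], dim(object@image)[1L], nrow(object@cells),
              tab[["Tumor"]], tab[["NonNeoplastic"]], tab[["Artifact"]]))
})

#' @describeIn DetectionSet-class compact display
#' @param object a `DetectionSet`
#' @export
setMethod("show", "DetectionSet", function(object) {
  cat(sprintf("DetectionSet: %d detections @ %.4f mpp", nrow(object@data), object@mpp))
  if ("label" %in% names(object@data)) {
    tab <- table(object@data$label)
    cat(" |", paste(sprintf("%s %d", names(tab), tab), collapse = ", "))
  }
  cat("\n")
})

#' @describeIn TCFResult-class compact display
#' @param object a `TCFResult`
#' @export
setMethod("show", "TCFResult", function(object) {
  cat(sprintf("TCFResult: tumor %d, non-neoplastic %d, ignored %d | cTCF %s | %s\n",
              object@nTumor, object@nNonneo, object@nIgnore,
              if (is.na(object@ctcf)) "undefined" else sprintf("%.3f", object@ctcf),
              if (isTRUE(object@adequate)) "adequate" else "inadequate"))
})

#' @describeIn AgreementResult-class compact display
#' @param object an `AgreementResult`
#' @export
setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult: weighted kappa %s (n = %d, k = %d), p = %s [%s]\n",
              if (is.na(object@kappa)) "undefined" else sprintf("%.3f", object@kappa),
              object@n, object@k,
              format.pval(object@pValue, digits = 3),
              object@method$null %||% "permutation"))
})

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
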