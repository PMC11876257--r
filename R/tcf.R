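# Tumor cellular fraction from classified nuclei, the molecular-adequacy
# gate, the tumor-area-fraction comparator, and the computational-vs-observer
# score comparison.

#' Compute the computational tumor cellular fraction (cTCF)
#'
#' Counts labeled detections inside the ROI and returns
#' `ctcf = nTumor / (nTumor + nNonneo)`; Ignore-class detections (artifacts,
#' red blood cells, mucus) never enter the ratio. When there are no
#' countable cells the cTCF is undefined and reported as `NA` (missing, not
#' zero) with `adequate = FALSE`. Adequacy flags are filled with
#' [assessAdequacy()] at the given thresholds.
#'
#' @param labels character vector of labels in
#'   `c("Tumor", "NonNeoplastic", "Ignore")`, or a labeled
#'   [DetectionSet-class].
#' @param minCells,minTcf adequacy thresholds (defaults 100 viable tumor
#'   cells and 20 percent TCF, both inclusive).
#' @return a [TCFResult-class].
#' @examples
#' computeCTCF(rep(c("Tumor", "NonNeoplastic", "Ignore"), c(30, 70, 10)))
#' @export
computeCTCF <- function(labels, minCells = 100, minTcf = 0.20) {
  if (is(labels, "DetectionSet")) {
    if (!"label" %in% names(labels@data))
      stop("DetectionSet has no labels; run classifyDetections() first")
    labels <- labels@data$label
  }
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASS_LEVELS)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(labels, levels = .CLASS_LEVELS))
  den <- tab[["Tumor"]] + tab[["NonNeoplastic"]]
  res <- new("TCFResult",
             nTumor = as.integer(tab[["Tumor"]]),
             nNonneo = as.integer(tab[["NonNeoplastic"]]),
             nIgnore = as.integer(tab[["Ignore"]]),
             ctcf = if (den > 0L) tab[["Tumor"]] / den else NA_real_,
             adequateCells = NA, adequateTcf = NA, adequate = NA,
             minCells = minCells, minTcf = minTcf)
  assessAdequacy(res, minCells = minCells, minTcf = minTcf)
}

#' Apply the molecular-adequacy gate
#'
#' A sample is adequate for molecular testing when it has at least
#' `minCells` viable tumor cells AND a TCF of at least `minTcf`; both
#' thresholds are inclusive. An undefined cTCF is inadequate.
#'
#' @param result a [TCFResult-class].
#' @param minCells minimum tumor-cell count (default 100).
#' @param minTcf minimum tumor cellular fraction (default 0.20).
#' @return the result with `adequateCells`, `adequateTcf` and `adequate`
#'   filled.
#' @export
assessAdequacy <- function(result, minCells = 100, minTcf = 0.20) {
  stopifnot(is(result, "TCFResult"))
  result@minCells <- minCells
  result@minTcf <- minTcf
  result@adequateCells <- result@nTumor >= minCells
  result@adequateTcf <- if (is.na(result@ctcf)) FALSE else result@ctcf >= minTcf
  result@adequate <- result@adequateCells && result@adequateTcf
  result
}

#' TCFResult accessors
#' @param result a [TCFResult-class].
#' @return `ctcfValue`: the fraction (`NA` when undefined); `tcfCounts`:
#'   named integer vector of the three class counts; `isAdequate`: the
#'   combined adequacy flag.
#' @name tcf-accessors
NULL

#' @rdname tcf-accessors
#' @export
ctcfValue <- function(result) result@ctcf

#' @rdname tcf-accessors
#' @export
tcfCounts <- function(result) c(Tumor = result@nTumor,
                                NonNeoplastic = result@nNonneo,
                                Ignore = result@nIgnore)

#' @rdname tcf-accessors
#' @export
isAdequate <- function(result) result@adequate

#' Tumor area fraction within the ROI
#'
#' Area-based comparator to the cell-count cTCF: the fraction of ROI area
#' covered by Tumor-labeled regions (regions are clipped to the ROI and
#' assumed non-overlapping). Because tumor nuclei are larger than
#' non-neoplastic ones, this statistic tracks the "illusion of size" that
#' inflates visual TCF estimates, and typically exceeds the count-based
#' fraction.
#'
#' @param polygons list of region polygons.
#' @param labels character vector parallel to `polygons` (`"Tumor"` marks
#'   tumor regions; anything else is non-tumor).
#' @param roi convex ROI polygon ring.
#' @return fraction of ROI area covered, in `[0, 1]`.
#' @export
tumorAreaFraction <- function(polygons, labels, roi) {
  roiArea <- .polygonArea(roi)
  if (roiArea <= 0) stop("zero-area ROI")
  stopifnot(length(polygons) == length(labels))
  tum <- which(labels == "Tumor")
  covered <- 0
  for (i in tum) {
    cl <- .clipPolygonConvex(polygons[[i]], roi)
    if (!is.null(cl)) covered <- covered + .polygonArea(cl)
  }
  min(covered / roiArea, 1)
}

#' Compare computational and observer TCF scores
#'
#' Per case, computes `delta = ctcf - mean(observer ratings)` on the percent
#' scale and classifies the case as `lower`, `higher` or `equal` ("equal"
#' means equal after rounding both scores to integer percent, the
#' granularity pathologists report at). Summarizes the direction counts and
#' the mean and SD of both score sets.
#'
#' @param ctcf named numeric vector (names = case ids) of computational TCF
#'   values in percent, or a data.frame with columns `case_id`, `ctcf`.
#' @param observers data.frame with `case_id` and one rating column per
#'   observer (percent), as from [simulateObservers()].
#' @return list with `perCase` (case_id, ctcf, observerMean, delta,
#'   direction), `counts` (named lower/higher/equal), and `summary`
#'   (means and SDs of both score sets).
#' @export
compareScores <- function(ctcf, observers) {
  if (is.data.frame(ctcf)) {
    stopifnot(all(c("case_id", "ctcf") %in% names(ctcf)))
    ctcf <- stats::setNames(ctcf$ctcf, ctcf$case_id)
  }
  if (!"case_id" %in% names(observers)) stop("observers must have a case_id column")
  missA <- setdiff(names(ctcf), observers$case_id)
  missB <- setdiff(observers$case_id, names(ctcf))
  if (length(missA) || length(missB))
    stop("case id mismatch; missing from observers: ",
         paste(missA, collapse = ", "), "; missing from ctcf: ",
         paste(missB, collapse = ", "))
  obs <- observers[match(names(ctcf), observers$case_id), , drop = FALSE]
  ratings <- as.matrix(obs[, setdiff(names(obs), "case_id"), drop = FALSE])
  obsMean <- rowMeans(ratings)
  delta <- unname(ctcf - obsMean)
  direction <- ifelse(round(ctcf) == round(obsMean), "equal",
                      ifelse(ctcf < obsMean, "lower", "higher"))
  perCase <- data.frame(case_id = names(ctcf), ctcf = unname(ctcf),
                        observerMean = unname(obsMean), delta = delta,
                        direction = unname(direction), stringsAsFactors = FALSE)
  counts <- c(lower = sum(direction == "lower"),
              higher = sum(direction == "higher"),
              equal = sum(direction == "equal"))
  list(perCase = perCase, counts = counts,
       summary = list(ctcfMean = mean(ctcf), ctcfSD = stats::sd(ctcf),
                      observerMean = mean(obsMean), observerSD = stats::sd(obsMean)))
}
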