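# Classical nucleus detection: hematoxylin-OD thresholding, hole filling,
# distance-transform watershed splitting and polygonization via EBImage.
# A stand-in for deep-learning detectors; their output can be brought in
# through importDetections() instead.

#' Detect nucleus candidates inside an ROI
#'
#' Thresholds the hematoxylin optical density from [deconvolveStains()],
#' fills holes, splits touching blobs with a distance-transform watershed,
#' polygonizes each object, applies the area gates and keeps detections
#' whose centroid lies inside the ROI polygon (centroid-in-ROI inclusion
#' rule, matching per-cell counting semantics). Polygons are clipped to the
#' ROI. Deterministic: the same image and parameters give the same result.
#'
#' @param img RGB array (`height x width x 3`, values in `[0, 1]`).
#' @param roi ROI polygon ring (n x 2 matrix, pixel coordinates); must be
#'   convex (the pen-marked region is modeled as such).
#' @param params a [DetectParams-class] from [detectParams()].
#' @param mpp microns per pixel for area conversion.
#' @return a [DetectionSet-class]; zero detections is a valid result.
#' @examples
#' scene <- generateScene(sceneSpec(widthPx = 256, heightPx = 256,
#'                                  nTumor = 5, nNonneo = 10, nArtifact = 0))
#' det <- detectNuclei(sceneImage(scene), sceneROI(scene))
#' det
#' @export
detectNuclei <- function(img, roi, params = detectParams(), mpp = 0.4416) {
  stopifnot(is(params, "DetectParams"))
  validObject(params)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  imgRect <- .rectRing(0, 0, w - 1, h - 1)
  if (is.null(.clipPolygonConvex(roi, imgRect)))
    stop("ROI does not intersect the image")
  od <- deconvolveStains(img)
  mask <- od$odH > params@odThreshold
  if (!any(mask)) return(.emptyDetections(mpp))
  eb <- EBImage::Image(t(mask) * 1)
  eb <- EBImage::fillHull(eb)
  dm <- EBImage::distmap(eb)
  labs <- EBImage::watershed(dm, tolerance = params@splitMinDistancePx, ext = 1L)
  labmat <- EBImage::imageData(labs)      # indexed [x, y]
  nlab <- max(labmat)
  if (nlab == 0L) return(.emptyDetections(mpp))
  contours <- EBImage::ocontour(labs)
  ids <- character(0); cx <- cy <- area <- odh <- ode <- numeric(0)
  polys <- list()
  for (L in seq_len(nlab)) {
    ind <- which(labmat == L, arr.ind = TRUE)      # cols: x, y (1-based)
    areaUm2 <- nrow(ind) * mpp^2
    if (areaUm2 < params@minAreaUm2 || areaUm2 > params@maxAreaUm2) next
    c0 <- c(mean(ind[, 1L]) - 1, mean(ind[, 2L]) - 1)
    if (!.pointsInPolygon(c0[1L], c0[2L], roi)) next
    poly <- contours[[L]]                          # (x, y), 0-based
    if (is.null(poly) || nrow(poly) < 3L) next
    poly <- .clipPolygonConvex(poly, roi)
    if (is.null(poly)) next
    pix <- cbind(ind[, 2L], ind[, 1L])             # (row, col) into y-x matrices
    k <- length(area) + 1L
    polys[[k]] <- poly
    cx[k] <- c0[1L]; cy[k] <- c0[2L]; area[k] <- areaUm2
    odh[k] <- mean(od$odH[pix]); ode[k] <- mean(od$odE[pix])
  }
  if (!length(area)) return(.emptyDetections(mpp))
  ord <- order(cy, cx)
  dat <- data.frame(id = sprintf("det-%04d", seq_along(ord)),
                    x = cx[ord], y = cy[ord], areaUm2 = area[ord],
                    meanOdH = odh[ord], meanOdE = ode[ord],
                    stringsAsFactors = FALSE)
  new("DetectionSet", data = dat, polygons = polys[ord], mpp = mpp)
}

.emptyDetections <- function(mpp) {
  new("DetectionSet",
      data = data.frame(id = character(0), x = numeric(0), y = numeric(0),
                        areaUm2 = numeric(0), meanOdH = numeric(0),
                        meanOdE = numeric(0), stringsAsFactors = FALSE),
      polygons = list(), mpp = mpp)
}

#' Import externally produced detections from GeoJSON
#'
#' Reads a QuPath-dialect GeoJSON FeatureCollection (e.g. exported from a
#' deep-learning nucleus detector), keeps features whose centroid lies
#' inside the ROI, clips their polygons to it and converts areas with the
#' configured resolution. Pre-existing classification names are preserved in
#' the `label` column as prior labels.
#'
#' @param path GeoJSON file of polygon features.
#' @param roi convex ROI polygon ring.
#' @param mpp microns per pixel.
#' @return a [DetectionSet-class]; an ROI excluding all features yields an
#'   empty set without error.
#' @export
importDetections <- function(path, roi, mpp = 0.4416) {
  feats <- readGeoJSON(path)
  nameMap <- c("Tumor" = "Tumor", "Non-neoplastic" = "NonNeoplastic",
               "Ignore" = "Ignore")
  ids <- character(0); cx <- cy <- area <- numeric(0)
  labs <- character(0); polys <- list()
  for (ft in feats) {
    mom <- .polygonMoments(ft$polygon)
    if (!.pointsInPolygon(mom$centroid[1L], mom$centroid[2L], roi)) next
    clipped <- .clipPolygonConvex(ft$polygon, roi)
    if (is.null(clipped)) next
    k <- length(area) + 1L
    polys[[k]] <- clipped
    ids[k] <- ft$id
    cx[k] <- mom$centroid[1L]; cy[k] <- mom$centroid[2L]
    area[k] <- .polygonArea(clipped) * mpp^2
    labs[k] <- unname(nameMap[ft$name] %||% ft$name)
  }
  dat <- data.frame(id = ids, x = cx, y = cy, areaUm2 = area,
                    meanOdH = rep(NA_real_, length(area)),
                    meanOdE = rep(NA_real_, length(area)),
                    label = labs, stringsAsFactors = FALSE)
  new("DetectionSet", data = dat, polygons = polys, mpp = mpp)
}

#' DetectionSet accessors
#'
#' @param det a [DetectionSet-class].
#' @return `detectionData`: the per-detection data.frame;
#'   `detectionPolygons`: the list of polygon outlines; `nDetections`: the
#'   number of detections; `detectionLabels`: the label column (or `NULL`).
#' @name detection-accessors
NULL

#' @rdname detection-accessors
#' @export
detectionData <- function(det) det@data

#' @rdname detection-accessors
#' @export
detectionPolygons <- function(det) det@polygons

#' @rdname detection-accessors
#' @export
nDetections <- function(det) nrow(det@data)

#' @rdname detection-accessors
#' @export
detectionLabels <- function(det) det@data$label
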