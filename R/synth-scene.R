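# Synthetic H&E scene generator. Nuclei are ellipses perturbed by low-order
# radial harmonics; placement is rejection sampling with a bounded retry
# budget; pairwise overlap is bounded conservatively via bounding circles.

.NVERT <- 24L

# polygon for one object: ellipse (a, b, theta) at (cx, cy) with radial
# perturbation 1 + sum_h amp_h * cos(h * t + phase_h), h in {2, 3}
.objectPolygon <- function(cx, cy, a, b, theta, amps, phases) {
  t <- seq(0, 2 * pi, length.out = .NVERT + 1L)[-(.NVERT + 1L)]
  pert <- 1 + amps[1L] * cos(2 * t + phases[1L]) + amps[2L] * cos(3 * t + phases[2L])
  ex <- a * cos(t) * pert
  ey <- b * sin(t) * pert
  x <- cx + ex * cos(theta) - ey * sin(theta)
  y <- cy + ex * sin(theta) + ey * cos(theta)
  cbind(x, y)
}

.drawObject <- function(cls, spec) {
  mppArea <- spec@mpp^2
  if (cls == "Artifact") {
    areaUm2 <- stats::runif(1, 15, 60)
    ar <- stats::runif(1, 1.5, 3)
    amps <- stats::runif(2, 0.08, 0.25)
  } else {
    meanArea <- if (cls == "Tumor") spec@tumorMeanAreaUm2 else spec@nonneoMeanAreaUm2
    cv <- max(spec@areaCV, 1e-6)
    sdlog <- sqrt(log(1 + cv^2))
    areaUm2 <- stats::rlnorm(1, meanlog = log(meanArea) - sdlog^2 / 2, sdlog = sdlog)
    # tumor nuclei are pleomorphic, non-neoplastic nuclei rounder
    ar <- if (cls == "Tumor") stats::runif(1, 1.2, 2.2) else stats::runif(1, 1.0, 1.3)
    amps <- stats::runif(2, 0, if (cls == "Tumor") 0.08 else 0.04)
  }
  areaPx <- areaUm2 / mppArea
  b <- sqrt(areaPx / (pi * ar))
  a <- ar * b
  theta <- stats::runif(1, 0, pi)
  phases <- stats::runif(2, 0, 2 * pi)
  list(cls = cls, a = a, b = b, theta = theta, amps = amps, phases = phases,
       # conservative bounding-circle radius
       rmax = a * (1 + sum(amps)))
}

#' Generate a synthetic H&E scene with ground truth
#'
#' Places `nTumor + nNonneo + nArtifact` objects with centroids uniformly
#' inside the rectangular ROI (inset `roiMarginPx` from the tile border),
#' subject to the pairwise-overlap bound, renders the tile with [renderHE()],
#' and returns image, per-object ground truth and ROI together. The result is
#' a pure function of the spec: the same spec reproduces the scene
#' bit-identically.
#'
#' @param spec a [SceneSpec-class] from [sceneSpec()].
#' @param maxTriesPerObject rejection-sampling retry budget per object;
#'   exhausting it raises an "overcrowded scene" error.
#' @return an [HEScene-class] object.
#' @examples
#' scene <- generateScene(sceneSpec(widthPx = 256, heightPx = 256,
#'                                  nTumor = 6, nNonneo = 14, nArtifact = 2))
#' trueTCF(scene)
#' @export
generateScene <- function(spec, maxTriesPerObject = 200L) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  set.seed(spec@seed)
  m <- spec@roiMarginPx
  roi <- .rectRing(m, m, spec@widthPx - 1 - m, spec@heightPx - 1 - m)
  classes <- rep(c("Tumor", "NonNeoplastic", "Artifact"),
                 times = c(spec@nTumor, spec@nNonneo, spec@nArtifact))
  placed <- vector("list", length(classes))
  cx <- cy <- rmax <- numeric(length(classes))
  for (i in seq_along(classes)) {
    obj <- .drawObject(classes[i], spec)
    if (m + obj$rmax >= spec@widthPx - 1 - m - obj$rmax ||
        m + obj$rmax >= spec@heightPx - 1 - m - obj$rmax)
      stop("overcrowded scene: object ", i, " does not fit inside the ROI")
    ok <- FALSE
    for (try in seq_len(maxTriesPerObject)) {
      px <- stats::runif(1, m + obj$rmax, spec@widthPx - 1 - m - obj$rmax)
      py <- stats::runif(1, m + obj$rmax, spec@heightPx - 1 - m - obj$rmax)
      if (i > 1L) {
        j <- seq_len(i - 1L)
        d <- sqrt((cx[j] - px)^2 + (cy[j] - py)^2)
        if (spec@maxOverlapFrac == 0) {
          if (any(d <= rmax[j] + obj$rmax + 1)) next
        } else {
          lens <- mapply(.circleLensArea, rmax[j], MoreArgs = list(r2 = obj$rmax),
                         d = d)
          smaller <- pi * pmin(rmax[j], obj$rmax)^2
          if (any(lens > spec@maxOverlapFrac * smaller)) next
        }
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("overcrowded scene: could not place object ", i, " of ",
           length(classes), " after ", maxTriesPerObject, " tries")
    cx[i] <- px; cy[i] <- py; rmax[i] <- obj$rmax
    placed[[i]] <- obj
  }
  polys <- lapply(seq_along(placed), function(i) {
    o <- placed[[i]]
    .objectPolygon(cx[i], cy[i], o$a, o$b, o$theta, o$amps, o$phases)
  })
  img <- renderHE(polys, classes, spec@widthPx, spec@heightPx,
                  noiseSD = 0.02, seed = spec@seed + 7919L)
  cells <- data.frame(
    id = sprintf("gt-%04d", seq_along(classes)),
    trueClass = classes,
    x = cx, y = cy,
    semiMajorPx = vapply(placed, `[[`, numeric(1), "a"),
    semiMinorPx = vapply(placed, `[[`, numeric(1), "b"),
    thetaRad = vapply(placed, `[[`, numeric(1), "theta"),
    areaUm2 = vapply(polys, .polygonArea, numeric(1)) * spec@mpp^2,
    stringsAsFactors = FALSE)
  new("HEScene", image = img, cells = cells, polygons = polys,
      roi = roi, spec = spec)
}

#' Scene accessors
#'
#' @param scene an [HEScene-class].
#' @return `sceneImage`: the RGB array; `sceneCells`: the ground-truth
#'   data.frame; `scenePolygons`: the list of object outlines; `sceneROI`:
#'   the ROI ring; `trueTCF`: the true tumor cellular fraction
#'   `nTumor / (nTumor + nNonneo)` recomputed from the emitted labels.
#' @name scene-accessors
NULL

#' @rdname scene-accessors
#' @export
sceneImage <- function(scene) scene@image

#' @rdname scene-accessors
#' @export
sceneCells <- function(scene) scene@cells

#' @rdname scene-accessors
#' @export
scenePolygons <- function(scene) scene@polygons

#' @rdname scene-accessors
#' @export
sceneROI <- function(scene) scene@roi

#' @rdname scene-accessors
#' @export
trueTCF <- function(scene) {
  tab <- table(factor(scene@cells$trueClass, levels = .TRUTH_LEVELS))
  den <- tab[["Tumor"]] + tab[["NonNeoplastic"]]
  if (den == 0L) return(NA_real_)
  tab[["Tumor"]] / den
}

#' Export scene ground truth as QuPath-dialect GeoJSON
#'
#' Writes one polygon Feature per object with
#' `properties.classification.name` set to `"Tumor"`, `"Non-neoplastic"` or
#' `"Ignore"` (artifacts), QuPath's naming.
#'
#' @param scene an [HEScene-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportGroundTruth <- function(scene, path) {
  nameMap <- c(Tumor = "Tumor", NonNeoplastic = "Non-neoplastic",
               Artifact = "Ignore")
  feats <- lapply(seq_len(nrow(scene@cells)), function(i) {
    list(polygon = scene@polygons[[i]],
         name = unname(nameMap[scene@cells$trueClass[i]]),
         id = scene@cells$id[i])
  })
  writeGeoJSON(feats, path)
}
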