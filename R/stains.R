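# Beer-Lambert two-stain optical-density model with fixed Ruifrok-Johnston
# style stain vectors for hematoxylin and eosin. The renderer and the
# deconvolution share the same basis, so render-then-invert is exact up to
# 8-bit quantization.

.stainMatrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  cbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)))
}

# transmitted light for concentration fields cH, cE (matrices height x width),
# quantized to 8-bit levels; returns height x width x 3 array in [0, 1]
.transmit <- function(cH, cE) {
  M <- .stainMatrix()
  img <- array(0, dim = c(nrow(cH), ncol(cH), 3L))
  for (k in 1:3) img[, , k] <- exp(-(cH * M[k, 1L] + cE * M[k, 2L]))
  round(img * 255) / 255
}

#' Unmix an H&E image into hematoxylin and eosin optical densities
#'
#' Inverts the Beer-Lambert transmission model against fixed hematoxylin and
#' eosin stain vectors (standard H&E unmixing basis): per-pixel optical
#' density `OD = -log(I / I0)` is projected onto the two stain vectors by
#' least squares, and negative loadings are clipped to zero. Saturated black
#' pixels are floored at intensity 1/255 before the log so the output stays
#' finite.
#'
#' @param img an RGB image: `height x width x 3` numeric array with values in
#'   `[0, 1]` (as returned by [generateScene()] or `png::readPNG()`), or
#'   8-bit integers in `[0, 255]`.
#' @return list with matrices `odH` and `odE` (height x width), non-negative.
#' @examples
#' scene <- generateScene(sceneSpec(nTumor = 5, nNonneo = 5, nArtifact = 0,
#'                                  widthPx = 128, heightPx = 128))
#' od <- deconvolveStains(sceneImage(scene))
#' range(od$odH)
#' @export
deconvolveStains <- function(img) {
  if (length(dim(img)) != 3L || dim(img)[3L] < 3L)
    stop("img must be a height x width x 3 RGB array")
  img <- img[, , 1:3, drop = FALSE]
  if (max(img) > 1) img <- img / 255
  img <- pmax(img, 1 / 255)            # floor saturated pixels
  od <- -log(img)
  M <- .stainMatrix()
  P <- solve(crossprod(M), t(M))       # 2 x 3 pseudo-inverse
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)        # npix x 3
  conc <- flat %*% t(P)                # npix x 2
  conc[conc < 0] <- 0
  list(odH = matrix(conc[, 1L], d[1L], d[2L]),
       odE = matrix(conc[, 2L], d[1L], d[2L]))
}

# Per-class stain concentrations used by the renderer. Non-neoplastic nuclei
# (lymphocyte-like) are rendered slightly more hyperchromatic than tumor
# nuclei. Artifact objects (red-blood-cell/debris-like) are eosin-dominant
# with a hematoxylin OD strictly below the nucleus minimum, yet above the
# stromal background so detectors still pick them up and the Ignore class is
# learnable.
.renderLevels <- function() {
  list(background = c(h = 0.03, e = 0.15),
       Tumor = c(h = 0.75, e = 0.05),
       NonNeoplastic = c(h = 1.00, e = 0.05),
       Artifact = c(h = 0.45, e = 1.10))
}

#' Render placed objects as an H&E-like RGB image
#'
#' Rasterizes each object polygon into per-pixel hematoxylin/eosin
#' concentration fields and transmits them through the Beer-Lambert model:
#' nuclei are hematoxylin-dominant on an eosin-tinted stromal background,
#' while artifact objects are eosin-dominant (high red, hematoxylin OD below
#' the nucleus minimum) so the Ignore class is separable by intensity.
#'
#' @param polygons list of `n x 2` polygon vertex matrices.
#' @param classes character vector of object classes parallel to `polygons`
#'   (`"Tumor"`, `"NonNeoplastic"` or `"Artifact"`).
#' @param widthPx,heightPx output size in pixels.
#' @param noiseSD standard deviation of Gaussian concentration noise added to
#'   both stain fields (0 disables; the default 0.02 gives mild texture).
#' @param seed seed for the noise field.
#' @return `height x width x 3` numeric array in `[0, 1]`, 8-bit quantized.
#' @examples
#' img <- renderHE(list(), character(0), 64, 64, noiseSD = 0)
#' dim(img)
#' @export
renderHE <- function(polygons, classes, widthPx, heightPx,
                     noiseSD = 0.02, seed = 1L) {
  stopifnot(length(polygons) == length(classes))
  lv <- .renderLevels()
  cH <- matrix(lv$background["h"], heightPx, widthPx)
  cE <- matrix(lv$background["e"], heightPx, widthPx)
  for (i in seq_along(polygons)) {
    cls <- classes[i]
    if (!cls %in% names(lv)) stop("unknown object class: ", cls)
    px <- .rasterizePolygon(polygons[[i]], width = widthPx, height = heightPx)
    if (nrow(px)) {
      idx <- cbind(px[, "row"], px[, "col"])
      cH[idx] <- lv[[cls]]["h"]
      cE[idx] <- lv[[cls]]["e"]
    }
  }
  if (noiseSD > 0) {
    set.seed(as.integer(seed))
    # pmax with the matrix first so dim attributes survive
    cH <- pmax(cH + matrix(stats::rnorm(length(cH), 0, noiseSD), nrow(cH)), 0)
    cE <- pmax(cE + matrix(stats::rnorm(length(cE), 0, noiseSD), nrow(cE)), 0)
  }
  .transmit(cH, cE)
}
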