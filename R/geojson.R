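# QuPath-dialect GeoJSON interchange. A "feature list" is a list of entries
# with elements: polygon (n x 2 vertex matrix, pixel units), name (character
# classification), and optionally id. Rings are closed on write (first
# vertex repeated) and re-opened on read.

#' Read a QuPath-dialect GeoJSON FeatureCollection
#'
#' Parses polygon features and their `properties.classification.name`.
#' Features without a classification are imported with the label
#' `"Unclassified"` (a warning is emitted). Non-polygon geometries raise an
#' error naming the (0-based) feature index.
#'
#' @param path a GeoJSON file.
#' @return list of features, each a list with `polygon` (n x 2 matrix,
#'   pixel coordinates), `name` (character) and `id`.
#' @export
readGeoJSON <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  feats <- doc$features %||% list()
  unclassified <- 0L
  out <- lapply(seq_along(feats), function(i) {
    ft <- feats[[i]]
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon"))
      stop("feature ", i - 1L, ": geometry is ",
           if (is.null(geom)) "missing" else geom$type,
           ", expected Polygon")
    ring <- geom$coordinates[[1L]]
    poly <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
    poly <- .asRing(poly)
    name <- ft$properties$classification$name
    if (is.null(name)) {
      unclassified <<- unclassified + 1L
      name <- "Unclassified"
    }
    list(polygon = poly, name = name,
         id = ft$id %||% ft$properties$name %||% sprintf("feature-%04d", i))
  })
  if (unclassified > 0L)
    warning(unclassified, " feature(s) had no classification; labeled 'Unclassified'")
  out
}

#' Write features as QuPath-dialect GeoJSON
#'
#' @param features list of features as returned by [readGeoJSON()]: each a
#'   list with `polygon` (n x 2 matrix), `name` and optionally `id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(features, path) {
  mkFeature <- function(ft, i) {
    poly <- .asRing(ft$polygon)
    ring <- lapply(seq_len(nrow(poly) + 1L), function(j) {
      k <- if (j > nrow(poly)) 1L else j
      c(poly[k, 1L], poly[k, 2L])
    })
    list(type = "Feature",
         id = ft$id %||% sprintf("feature-%04d", i),
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(objectType = "detection",
                           classification = list(name = ft$name %||% "Unclassified")))
  }
  doc <- list(type = "FeatureCollection",
              features = lapply(seq_along(features),
                                function(i) mkFeature(features[[i]], i)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

# convert a DetectionSet (with optional labels) to a feature list
.detectionsToFeatures <- function(det) {
  d <- det@data
  nameMap <- c(Tumor = "Tumor", NonNeoplastic = "Non-neoplastic", Ignore = "Ignore")
  lapply(seq_len(nrow(d)), function(i) {
    nm <- if ("label" %in% names(d)) unname(nameMap[d$label[i]] %||% d$label[i])
          else "Unclassified"
    list(polygon = det@polygons[[i]], name = nm, id = d$id[i])
  })
}

#' Write a DetectionSet as QuPath-dialect GeoJSON
#'
#' @param det a [DetectionSet-class]; if labeled, classification names follow
#'   QuPath conventions (`Tumor`, `Non-neoplastic`, `Ignore`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDetections <- function(det, path) {
  writeGeoJSON(.detectionsToFeatures(det), path)
}
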