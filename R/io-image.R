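#' Read / write an RGB image tile
#'
#' PNG (via the png package) or TIFF (via the tiff package, when installed).
#' Images are `height x width x 3` arrays in `[0, 1]`; grayscale input is
#' expanded to three channels and an alpha channel is dropped.
#'
#' @param path image file; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param img RGB array to write.
#' @return `readImageTile`: the array; `writeImageTile`: `path`, invisibly.
#' @export
readImageTile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE))
                    stop("the 'tiff' package is needed to read TIFF files")
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' @rdname readImageTile
#' @export
writeImageTile <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = , tiff = {
           if (!requireNamespace("tiff", quietly = TRUE))
             stop("the 'tiff' package is needed to write TIFF files")
           tiff::writeTIFF(img, path)
         },
         stop("unsupported image format: .", ext))
  invisible(path)
}
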