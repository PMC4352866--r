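#' Read an 8-bit RGB image
#'
#' Reads PNG or TIFF into the internal representation: an H x W x 3 array
#' of reals in \[0, 1\]. Gray-scale files are replicated across the three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An H x W x 3 array in \[0, 1\].
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (PNG and TIFF are supported)"))
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2) img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  check_rgb_image(img)
  img
}

#' Write a matrix as an 8-bit gray PNG
#'
#' Min-max normalises the matrix and writes it as an 8-bit gray-scale PNG
#' preview, e.g. for saliency maps.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @export
write_image_gray <- function(m, path) {
  png::writePNG(minmax01(m), path)
  invisible(path)
}
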