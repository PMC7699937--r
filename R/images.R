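#' Load a micrograph as a normalized intensity array
#'
#' Reads a PNG, TIFF or JPEG image and returns intensities in `[0, 1]`
#' (8- and 16-bit inputs are normalized by the readers' dtype maximum).
#' Color images come back as an `n x m x 3` array (alpha dropped),
#' grey images as an `n x m` matrix; rows are image rows (y), columns x.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Numeric array (`n x m x 3`) or matrix (`n x m`) in `[0, 1]`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read image file: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L && dim(img)[3L] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L) {
    img <- img[, , 1L]
  }
  if (any(!is.finite(img))) stop("image contains non-finite pixel values")
  img <- pmin(pmax(img, 0), 1)
  img
}

#' Write a grey or RGB `[0, 1]` array as PNG
#'
#' @param img Matrix or `n x m x 3` array with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img * 1.0, 0), 1), target = path)
  invisible(path)
}

#' @rdname channels
#' @export
red_channel <- function(rgb) {
  assert_rgb(rgb)
  rgb[, , 1L]
}

#' Extract RGB-derived channels
#'
#' `red_channel` returns the red plane; `saturation_channel` returns the HSV
#' saturation `S = (max - min) / max` (hexcone model, 0 where `max = 0`), so
#' a pure grey image has saturation identically zero.
#'
#' @param rgb `n x m x 3` array in `[0, 1]`.
#' @return `n x m` matrix in `[0, 1]`.
#' @name channels
#' @export
saturation_channel <- function(rgb) {
  assert_rgb(rgb)
  mx <- pmax(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L])
  mn <- pmin(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  matrix(s, nrow = nrow(rgb[, , 1L]))
}

#' Min-max rescale to the unit interval
#'
#' Constant inputs (range numerically zero) map to all zeros so that a
#' degenerate preprocessed image still lives on the fixed `[0, 1]`
#' binarization domain.
#'
#' @param x Numeric array.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
rescale01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("cannot rescale non-finite values")
  if (rng[2L] - rng[1L] <= .Machine$double.eps * max(1, abs(rng[2L]))) {
    return(array(0, dim = dim(x)))
  }
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(arg, " must be a numeric matrix")
  }
  if (any(!is.finite(img))) stop(arg, " contains non-finite pixel values")
  invisible(img)
}

assert_rgb <- function(rgb, arg = "rgb") {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L) {
    stop(arg, " must be an n x m x 3 array")
  }
  if (any(!is.finite(rgb))) stop(arg, " contains non-finite pixel values")
  invisible(rgb)
}
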