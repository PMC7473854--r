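# Eye-pigmentation quantification: dark-pixel masking of pre-cropped
# grayscale eye images and normalization against the most pigmented eye.

#' Count pigmented pixels by intensity thresholding
#'
#' Reimplements the thresholding mask used on pre-cropped 8-bit grayscale
#' eye images: a pixel is pigmented when its intensity lies in
#' `[low, high]`, inclusive on both bounds (the semantics of an ImageJ-style
#' `setThreshold(1, 30)` on a black-background mask). Images are assumed
#' already cropped to the eye (conventionally 365 x 365 pixels); no
#' segmentation is performed.
#'
#' @param image integer matrix/array of 8-bit intensities (0-255). A
#'   three-channel array is converted to grayscale with the standard
#'   luminance weights (0.299 R + 0.587 G + 0.114 B, rounded) when
#'   `convert = TRUE`, otherwise it is an error. Numeric matrices in
#'   \[0, 1\] (as returned by `png::readPNG`) are rescaled to 0-255 when
#'   `convert = TRUE`.
#' @param low,high inclusive intensity bounds of the mask (defaults 1, 30).
#' @param convert allow RGB and \[0, 1\]-scaled inputs (default FALSE).
#' @return Integer count of masked pixels.
#' @export
mask_pigment <- function(image, low = 1L, high = 30L, convert = FALSE) {
  if (is.array(image) && base::length(dim(image)) == 3L) {
    if (!convert)
      stop("multi-channel image: pass convert = TRUE for luminance conversion")
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  if (!is.matrix(image)) stop("image must be a matrix or 3-channel array")
  mx <- max(image)
  if (mx <= 1 && !all(image == as.integer(image))) {
    if (!convert)
      stop("image appears scaled to [0, 1]: pass convert = TRUE")
    image <- image * 255
  }
  image <- round(image)
  if (min(image) < 0 || max(image) > 255)
    stop("image intensities outside 8-bit range 0-255")
  sum(image >= low & image <= high)
}

#' Normalize a masked-pixel count to a pigmentation score
#'
#' Maps a masked-pixel count to a unit phenotype score relative to the most
#' pigmented reference eye of the batch:
#' `(max_ref - masked_pixels) / max_ref`. The reference eye scores 0
#' (fully pigmented, no knockout phenotype) and a fully unpigmented eye
#' scores 1. Counts exceeding `max_ref` are clipped to 0 with a message;
#' `max_ref` is a required argument so batch scores are reproducible rather
#' than dependent on which images happened to be processed.
#'
#' @param masked_pixels non-negative integer count(s).
#' @param max_ref masked-pixel count of the most pigmented reference eye
#'   (> 0).
#' @return Score(s) in \[0, 1\].
#' @export
normalize_pigment <- function(masked_pixels, max_ref) {
  if (max_ref <= 0) stop("max_ref must be positive")
  if (any(masked_pixels < 0)) stop("masked_pixels must be non-negative")
  over <- masked_pixels > max_ref
  if (any(over))
    message(sprintf("%d measurement(s) exceed max_ref; clipped to score 0",
                    sum(over)))
  pmax((max_ref - masked_pixels) / max_ref, 0)
}

#' Read an eye image as an 8-bit grayscale matrix
#'
#' Thin reader over the `png`/`tiff` packages returning a 0-255 integer
#' matrix ready for [mask_pigment()] (RGB inputs are converted by
#' luminance).
#'
#' @param path PNG or TIFF path.
#' @return Integer matrix of intensities.
#' @export
read_eye_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext))
  if (base::length(dim(img)) == 3L)
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  round(img * 255)
}
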