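## Membrane-localization quantification from calibrated images.
##
## The whole-cell area is the logical complement of an externally supplied
## background annotation. The membrane band is obtained by dilating the
## background by a Euclidean disk whose radius is the micron dilation
## distance converted to pixels (rounded to nearest), intersected with the
## cell area - i.e. the band of cell pixels within the dilation distance
## of the background, just inside the cell edge. At the reference
## calibration of 0.1083 um/pixel a 2 um dilation gives a radius of
## round(18.47) = 18 px.

#' Whole-cell mask from a background annotation
#'
#' The inverse of the background annotation, classified as the whole-cell
#' area. An all-background image yields an empty cell mask (flagged with a
#' warning).
#'
#' @param backgroundMask Logical matrix, `TRUE` = background.
#' @return Logical matrix, `TRUE` = cell.
#' @export
cellMaskFromBackground <- function(backgroundMask) {
  stopifnot(is.matrix(backgroundMask))
  mode(backgroundMask) <- "logical"
  cm <- !backgroundMask
  if (!any(cm)) warning("all-background annotation: empty cell mask")
  cm
}

# exact Euclidean disk structuring element: offsets with dx^2+dy^2 <= r^2
.discKernel <- function(r) {
  d <- seq(-r, r)
  k <- outer(d^2, d^2, `+`) <= r^2
  storage.mode(k) <- "double"
  k
}

#' Membrane band mask
#'
#' Morphological dilation of the background annotation by a Euclidean disk
#' of radius `round(dilationUm / umPerPixel)` pixels, intersected with the
#' cell mask. A pixel is in the band iff its Euclidean distance to the
#' nearest background pixel is at most the radius.
#'
#' @param backgroundMask Logical matrix, `TRUE` = background.
#' @param umPerPixel Pixel size in micrometres.
#' @param dilationUm Dilation distance in micrometres (default 2).
#' @return Logical matrix, `TRUE` = membrane band.
#' @export
membraneBand <- function(backgroundMask, umPerPixel, dilationUm = 2.0) {
  stopifnot(is.matrix(backgroundMask), umPerPixel > 0, dilationUm > 0)
  r <- as.integer(round(dilationUm / umPerPixel))
  if (r < 1L)
    stop("dilation radius rounds to 0 px (", dilationUm, " um at ",
         umPerPixel, " um/pixel): calibration too coarse")
  mode(backgroundMask) <- "logical"
  bg <- backgroundMask
  storage.mode(bg) <- "double"
  dil <- EBImage::dilate(bg, .discKernel(r))
  (dil > 0.5) & !backgroundMask
}

#' Membrane localization of a labeled image
#'
#' Computes the whole-cell and membrane-band masks and two localization
#' readouts: `membraneFraction`, the integrated intensity in the band over
#' the integrated intensity in the whole cell (bounded in `[0, 1]`,
#' headline output), and `meanIntensityRatio`, the mean band intensity
#' over the mean cell intensity. An image with zero total cell intensity
#' yields `NA` readouts with a warning.
#'
#' @param image A [LabeledImage-class].
#' @param dilationUm Dilation distance in micrometres (default 2).
#' @return A [LocalizationResult-class].
#' @export
localizationRatio <- function(image, dilationUm = 2.0) {
  stopifnot(is(image, "LabeledImage"))
  cm <- cellMaskFromBackground(backgroundMask(image))
  if (!any(cm))
    stop("empty cell mask: nothing to quantify")
  band <- membraneBand(backgroundMask(image), umPerPixel(image), dilationUm)
  I <- imageIntensity(image)
  totCell <- sum(I[cm])
  if (totCell <= 0) {
    warning("zero total cell intensity: localization undefined")
    mf <- NA_real_; mr <- NA_real_
  } else {
    mf <- sum(I[band]) / totCell
    mr <- if (any(band)) mean(I[band]) / mean(I[cm]) else 0
  }
  new("LocalizationResult", cellMask = cm, membraneMask = band,
      membraneFraction = mf, meanIntensityRatio = mr)
}

#' Read a labeled image from TIFF files
#'
#' @param imagePath Path to the single-channel intensity TIFF.
#' @param backgroundPath Path to the background-mask TIFF (nonzero =
#'   background).
#' @param umPerPixel Pixel size in micrometres.
#' @param scale Factor converting stored `[0, 1]` grayscale back to
#'   intensity units (default 65535, i.e. 16-bit counts).
#' @return A [LabeledImage-class].
#' @export
readLabeledImage <- function(imagePath, backgroundPath, umPerPixel,
                             scale = 65535) {
  I <- as.matrix(EBImage::imageData(EBImage::readImage(imagePath)))
  bg <- as.matrix(EBImage::imageData(EBImage::readImage(backgroundPath)))
  LabeledImage(I * scale, bg > 0.5, umPerPixel)
}

#' Write a labeled image to 16-bit TIFF files
#'
#' @param image A [LabeledImage-class].
#' @param imagePath,backgroundPath Output paths.
#' @param scale Intensity divisor before storing as `[0, 1]` grayscale
#'   (default 65535); intensities above `scale` are clipped.
#' @return Invisibly `NULL`.
#' @export
writeLabeledImage <- function(image, imagePath, backgroundPath,
                              scale = 65535) {
  I <- pmin(imageIntensity(image) / scale, 1)
  EBImage::writeImage(EBImage::Image(I), imagePath, type = "tiff",
                      bits.per.sample = 16L)
  bg <- backgroundMask(image) * 1
  EBImage::writeImage(EBImage::Image(bg), backgroundPath, type = "tiff",
                      bits.per.sample = 16L)
  invisible(NULL)
}
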