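#' Read a plate photograph
#'
#' Reads a JPEG, PNG or TIFF plate photograph into a raster array with values
#' on the 0--255 scale, optionally applying the manual pre-processing steps
#' used before analysis: a small rotation to square up the well rows, a crop
#' to the plate edges, and a linear exposure offset. All pre-processing is
#' explicit -- nothing is auto-detected -- so a given file plus a given set of
#' options always produces the same raster.
#'
#' @param path Path to a JPEG/PNG/TIFF image.
#' @param rotation_deg Rotation in degrees (counter-clockwise, white fill),
#'   applied before cropping. Default 0.
#' @param crop_box Optional integer vector `(x0, y0, x1, y1)` of the pixel
#'   region to keep (inclusive), applied after rotation.
#' @param exposure_offset Gray levels added uniformly to every channel
#'   (clipped to 0--255). Default 0, so synthetic fixtures pass through
#'   unchanged.
#' @return For color images, a numeric array `[y, x, channel]`; for grayscale
#'   files, a numeric matrix `[y, x]`. Values in 0--255.
#' @export
read_plate_image <- function(path, rotation_deg = 0, crop_box = NULL,
                             exposure_offset = 0) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  img <- EBImage::readImage(path)
  if (rotation_deg != 0)
    img <- EBImage::rotate(img, rotation_deg, bg.col = "white")
  a <- EBImage::imageData(img)
  # EBImage stores [x, y(, channel)] in 0-1; transpose to [y, x(, channel)]
  a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
  a <- a * 255
  if (!is.null(crop_box)) {
    if (length(crop_box) != 4L)
      stop("`crop_box` must be (x0, y0, x1, y1)", call. = FALSE)
    x <- crop_box[1]:crop_box[3]
    y <- crop_box[2]:crop_box[4]
    if (min(y) < 1 || max(y) > dim(a)[1] || min(x) < 1 || max(x) > dim(a)[2])
      stop("`crop_box` exceeds image bounds", call. = FALSE)
    a <- if (length(dim(a)) == 2L) a[y, x, drop = FALSE] else a[y, x, , drop = FALSE]
  }
  if (exposure_offset != 0)
    a <- pmin(pmax(a + exposure_offset, 0), 255)
  a
}

#' Convert a raster to an 8-bit grayscale plate image
#'
#' Color rasters are collapsed to luminance with the ITU-R BT.601 weights
#' (0.299 R + 0.587 G + 0.114 B) and quantized to integers 0--255; a
#' single-channel raster is quantized as-is. The conversion is deterministic.
#'
#' @param raster A `[y, x]` matrix or `[y, x, 3]` (or `[y, x, 4]`, alpha
#'   dropped) array. Values may be on the 0--1 or the 0--255 scale; 0--1
#'   input is rescaled.
#' @param scale Optional [pixel_scale()] to attach.
#' @return An object of class `plate_image`: list with `pixels` (integer
#'   matrix `[y, x]`, values 0--255), `bit_depth = 8`, and `scale`.
#' @examples
#' to_grayscale_8bit(matrix(1, 2, 2))$pixels # all 255
#' @export
to_grayscale_8bit <- function(raster, scale = NULL) {
  d <- dim(raster)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("unsupported raster: expected a [y, x] matrix or [y, x, channels] array",
         call. = FALSE)
  if (length(d) == 3L) {
    if (d[3] == 4L) raster <- raster[, , 1:3, drop = FALSE] # drop alpha
    else if (d[3] == 1L) raster <- raster[, , 1]
    else if (d[3] != 3L)
      stop(sprintf("unsupported channel count: %d", d[3]), call. = FALSE)
  }
  # normalize to 0-255 if the raster came in on the 0-1 scale
  mx <- max(raster)
  if (mx <= 1 && min(raster) >= 0) raster <- raster * 255
  gray <- if (length(dim(raster)) == 3L) {
    0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3]
  } else {
    raster
  }
  px <- matrix(as.integer(pmin(pmax(round(gray), 0), 255)),
               nrow = d[1], ncol = d[2])
  plate_image(px, scale)
}

#' Construct a plate image from an 8-bit pixel matrix
#'
#' @param pixels Integer matrix `[y, x]` with values in 0--255.
#' @param scale Optional [pixel_scale()].
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, scale = NULL) {
  if (!is.matrix(pixels))
    stop("`pixels` must be a matrix", call. = FALSE)
  if (any(pixels < 0 | pixels > 255))
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (!is.null(scale)) stopifnot(inherits(scale, "pixel_scale"))
  structure(list(pixels = pixels, bit_depth = 8L, scale = scale),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("plate_image: %d x %d px, 8-bit grayscale%s\n",
              ncol(x$pixels), nrow(x$pixels),
              if (is.null(x$scale)) ""
              else sprintf(", %.6g mm/px", x$scale$mm_per_px)))
  invisible(x)
}

#' Write an 8-bit grayscale plate image to PNG
#'
#' @param image A [plate_image()] or an integer pixel matrix `[y, x]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(image, path) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  png::writePNG(px / 255, path)
  invisible(path)
}
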