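#' Physical pixel calibration
#'
#' Binds a linear calibration in pixels per millimetre to its derived pixel
#' area. The study constant for the source EUS frames is 12.2674 pixels/mm,
#' i.e. one pixel covers \eqn{1/12.2674^2 \approx 0.0066450} mm\eqn{^2} and one
#' mm\eqn{^2} holds \eqn{12.2674^2 \approx 150.489} pixels.
#'
#' @param pixels_per_mm Positive scalar, pixels per millimetre.
#' @return An object of class `calibration_spec` with fields `pixels_per_mm`
#'   and `pixel_area_mm2`.
#' @examples
#' cal <- calibration_spec(12.2674)
#' cal$pixel_area_mm2 # ~0.006645 mm^2
#' @export
calibration_spec <- function(pixels_per_mm = 12.2674) {
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1L ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0) {
    stop("'pixels_per_mm' must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(
      pixels_per_mm = as.numeric(pixels_per_mm),
      pixel_area_mm2 = 1 / pixels_per_mm^2
    ),
    class = "calibration_spec"
  )
}

#' @export
print.calibration_spec <- function(x, ...) {
  cat(sprintf(
    "Calibration: %.6g px/mm (pixel area %.6g mm^2, %.6g px/mm^2)\n",
    x$pixels_per_mm, x$pixel_area_mm2, x$pixels_per_mm^2
  ))
  invisible(x)
}

#' Calibrated 8-bit grayscale image
#'
#' An 8-bit B-mode still frame together with its physical calibration. Pixel
#' coordinates throughout the package are `(row, col)`, 0-based, with the
#' pixel center at integer coordinates; `gray` is stored as an integer matrix
#' with `height` rows and `width` columns.
#'
#' @param gray Integer matrix of gray values in `[0, 255]` (rows = image rows).
#' @param calibration A [calibration_spec()].
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(gray, calibration = calibration_spec()) {
  stopifnot(inherits(calibration, "calibration_spec"))
  if (!is.matrix(gray) || nrow(gray) < 1L || ncol(gray) < 1L) {
    stop("'gray' must be a matrix with at least one row and column", call. = FALSE)
  }
  g <- as.vector(gray)
  if (anyNA(g) || any(g != as.integer(g)) || any(g < 0) || any(g > 255)) {
    stop("gray values must be integers in [0, 255] (8-bit)", call. = FALSE)
  }
  storage.mode(gray) <- "integer"
  structure(
    list(
      gray = gray,
      width = ncol(gray),
      height = nrow(gray),
      calibration = calibration
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "Calibrated 8-bit image: %d x %d px at %.6g px/mm, gray range [%d, %d]\n",
    x$width, x$height, x$calibration$pixels_per_mm,
    min(x$gray), max(x$gray)
  ))
  invisible(x)
}

#' Load an image file as a calibrated 8-bit grayscale frame
#'
#' Reads a PNG or JPEG still frame and attaches a physical calibration. Color
#' inputs are converted to 8-bit luminance with ITU-R BT.601 weights
#' (0.299, 0.587, 0.114) on the 0-255 channel values, rounded half-up; an
#' alpha channel, if present, is ignored. Decoding is deterministic: loading
#' the same file twice yields identical pixel grids.
#'
#' @param path Path to a PNG or JPEG file.
#' @param calibration A [calibration_spec()]; defaults to the EUS study
#'   constant 12.2674 px/mm.
#' @return A [calibrated_image()].
#' @export
load_grayscale_image <- function(path, calibration = calibration_spec()) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("image file not found: '%s'", as.character(path)[1]), call. = FALSE)
  }
  magic <- readBin(path, "raw", n = 3L)
  arr <- if (length(magic) >= 3L &&
             identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    jpeg::readJPEG(path)
  } else if (length(magic) >= 3L &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e)))) {
    png::readPNG(path)
  } else {
    stop(sprintf("cannot decode '%s': not a PNG or JPEG file", path), call. = FALSE)
  }
  # readers return values in [0,1]; 8-bit samples are k/255 exactly
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      lum <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      lum <- arr[, , 1]
    }
  } else {
    lum <- arr
  }
  scaled <- lum * 255
  g <- floor(scaled + 0.5) # round half-up
  # a >8-bit source yields fractions that are not k/255; luminance mixing of
  # 8-bit channels stays within rounding of the weighted integer sum
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L) {
    if (max(abs(scaled - g)) > 1e-6) {
      stop(sprintf("'%s' has bit depth > 8 after conversion; only 8-bit input is supported", path),
           call. = FALSE)
    }
  }
  calibrated_image(matrix(as.integer(g), nrow = nrow(lum)), calibration)
}

#' Export a region mask as an audit PNG
#'
#' Writes a 0/255 8-bit PNG of a mask, for visual audit of segmentations.
#'
#' @param mask Logical mask matrix (see [rasterize_polygon()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), target = path)
  invisible(path)
}
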