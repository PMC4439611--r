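#' 2D grayscale MR image
#'
#' Lightweight container for a single 2D slice: a numeric matrix of
#' non-negative intensities (arbitrary MR units) indexed `[row, col]`,
#' plus the in-plane pixel spacing in mm/pixel.
#'
#' @param pixels numeric matrix of intensities; must be finite and
#'   non-negative, with at least 8 rows and 8 columns.
#' @param pixel_spacing in-plane spacing in mm/pixel (scalar, default 1).
#' @return an object of class `image2d` with fields `pixels`, `height`,
#'   `width`, `pixel_spacing`.
#' @examples
#' img <- image2d(matrix(10, 16, 16))
#' dim(img)
#' @export
image2d <- function(pixels, pixel_spacing = 1.0) {
  pixels <- as_pixels(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("image2d: image must be at least 8 x 8 pixels")
  if (!all(is.finite(pixels)))
    stop("image2d: intensities must be finite")
  if (min(pixels) < 0)
    stop("image2d: intensities must be non-negative")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("image2d: pixel_spacing must be a positive scalar")
  structure(list(pixels = pixels,
                 height = nrow(pixels),
                 width = ncol(pixels),
                 pixel_spacing = as.numeric(pixel_spacing)),
            class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
as.matrix.image2d <- function(x, ...) x$pixels

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d, intensity range [%.4g, %.4g], %.3g mm/px\n",
              x$height, x$width, min(x$pixels), max(x$pixels),
              x$pixel_spacing))
  invisible(x)
}

#' Binary segmentation mask
#'
#' A strictly 0/1 integer matrix with the same shape as its source image.
#'
#' @param pixels matrix (logical or numeric in \{0, 1\}).
#' @return object of class `binary_mask` with field `pixels` (integer 0/1).
#' @examples
#' m <- binary_mask(matrix(c(0, 1), 8, 8))
#' sum(m$pixels)
#' @export
binary_mask <- function(pixels) {
  pixels <- as_pixels(pixels)
  if (is.logical(pixels)) {
    storage.mode(pixels) <- "integer"
  } else {
    if (!all(pixels %in% c(0, 1)))
      stop("binary_mask: values must be strictly 0 or 1")
    storage.mode(pixels) <- "integer"
  }
  structure(list(pixels = pixels), class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$pixels)

#' @export
as.matrix.binary_mask <- function(x, ...) x$pixels

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Segmentation result record
#'
#' Bundles the final foreground mask, its ordered outer boundary, the
#' method that produced it, the iteration count, and (optionally) the
#' Dice score against a reference mask.
#'
#' @param mask a [binary_mask()].
#' @param boundary integer matrix of (row, col) boundary pixels in closed
#'   polygon order, or `NULL` for an empty mask.
#' @param method_name method label, e.g. `"acwe"`.
#' @param iterations_run number of iterations the method executed.
#' @param dice optional Dice coefficient in `[0, 1]`.
#' @return object of class `segmentation_result`.
#' @export
segmentation_result <- function(mask, boundary, method_name,
                                iterations_run, dice = NA_real_) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.na(dice) && (dice < 0 || dice > 1))
    stop("segmentation_result: dice must lie in [0, 1]")
  structure(list(mask = mask,
                 boundary = boundary,
                 method_name = method_name,
                 iterations_run = as.integer(iterations_run),
                 dice = dice),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result [%s]: %d foreground px, %d iterations%s\n",
              x$method_name, sum(x$mask$pixels), x$iterations_run,
              if (is.na(x$dice)) "" else sprintf(", Dice %.4f", x$dice)))
  invisible(x)
}
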