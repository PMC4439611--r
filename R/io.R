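#' Load a 2D grayscale image
#'
#' Reads a single 2D grayscale frame from DICOM, PNG, or TIFF into an
#' [image2d()]. PNG/TIFF intensities are returned on their native integer
#' scale (e.g. 0-65535 for 16-bit). For DICOM, rescale slope/intercept are
#' applied if present and the result is clamped at 0, since MR magnitude
#' intensities are physically non-negative. Multi-frame or multi-channel
#' (RGB) input is rejected.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"dicom"`, `"png"`, `"tiff"`. `"auto"`
#'   sniffs the DICM magic bytes, then falls back to the file extension.
#' @return an [image2d()].
#' @export
load_image <- function(path, format = c("auto", "dicom", "png", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("load_image: file does not exist: ", path)
  if (format == "auto") {
    format <- sniff_format(path)
    if (is.na(format))
      stop("load_image: cannot determine format of ", path)
  }
  switch(format,
         dicom = read_dicom_image(path),
         png = read_png_image(path),
         tiff = read_tiff_image(path))
}

sniff_format <- function(path) {
  head <- readBin(path, "raw", n = 132L)
  if (length(head) >= 132L && identical(head[129:132], charToRaw("DICM")))
    return("dicom")
  if (length(head) >= 8L &&
      identical(head[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                    0x0d, 0x0a, 0x1a, 0x0a))))
    return("png")
  if (length(head) >= 4L &&
      (identical(head[1:4], as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
       identical(head[1:4], as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))))
    return("tiff")
  ext <- tolower(tools::file_ext(path))
  switch(ext, dcm = "dicom", png = "png", tif = , tiff = "tiff", NA_character_)
}

read_png_image <- function(path) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 1L)
      stop("load_image: multi-channel (RGB/alpha) PNG is unsupported")
    a <- a[, , 1L]
  }
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  image2d(round(a * (2^depth - 1)))
}

read_tiff_image <- function(path) {
  a <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] > 1L)
      stop("load_image: multi-channel (RGB/alpha) TIFF is unsupported")
    a <- a[, , 1L]
  }
  image2d(pmax(a, 0))
}

#' Save an image as 16-bit grayscale TIFF or 8-bit PNG
#'
#' Intensities are rounded to integers. TIFF output is 16-bit (values must
#' fit 0-65535); PNG output is 8-bit (values must fit 0-255). Integer-valued
#' images round-trip exactly through [load_image()].
#'
#' @param image an [image2d()] or numeric matrix.
#' @param path output path; extension selects the container (.tif/.tiff/.png).
#' @return `invisible(path)`.
#' @export
save_image <- function(image, path) {
  px <- round(as_pixels(image))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(px) > 65535 || min(px) < 0)
      stop("save_image: 16-bit TIFF requires intensities in [0, 65535]")
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(px) > 255 || min(px) < 0)
      stop("save_image: 8-bit PNG requires intensities in [0, 255]")
    png::writePNG(px / 255, path)
  } else stop("save_image: unsupported extension .", ext)
  invisible(path)
}

#' Save / load a binary mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNG with values \{0, 255\};
#' load(save(x)) is bit-exact.
#'
#' @param mask a [binary_mask()].
#' @param path PNG path.
#' @return `invisible(path)` for save; a [binary_mask()] for load.
#' @export
save_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$pixels + 0.0, path)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  binary_mask(a > 0.5)
}

# ---- minimal DICOM reader --------------------------------------------------
# Single-frame grayscale DICOM, little-endian, explicit or implicit VR.
# Parses only the handful of Image Pixel module tags the pipeline needs.

dcm_u16 <- function(raw, off) {
  as.integer(raw[off]) + 256L * as.integer(raw[off + 1L])
}
dcm_u32 <- function(raw, off) {
  as.numeric(raw[off]) + 256 * as.numeric(raw[off + 1L]) +
    65536 * as.numeric(raw[off + 2L]) + 16777216 * as.numeric(raw[off + 3L])
}

read_dicom_image <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("load_image: not a DICOM file (missing DICM preamble): ", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  ts_implicit <- FALSE
  tags <- list()
  off <- 133L
  n <- length(raw)
  while (off + 7L <= n) {
    group <- dcm_u16(raw, off)
    elem <- dcm_u16(raw, off + 2L)
    explicit <- (group == 2L) || !ts_implicit
    if (explicit) {
      vr <- rawToChar(raw[(off + 4L):(off + 5L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw, off + 8L)
        val_off <- off + 12L
      } else {
        len <- dcm_u16(raw, off + 6L)
        val_off <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, off + 4L)
      val_off <- off + 8L
    }
    if (len >= 4294967295 || (!is.na(vr) && vr == "SQ"))
      stop("load_image: DICOM sequences / undefined lengths are unsupported")
    value <- if (len > 0) raw[val_off:(val_off + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    tags[[key]] <- value
    if (key == "0002,0010" &&
        grepl("^1\\.2\\.840\\.10008\\.1\\.2$", trim_dcm_str(value)))
      ts_implicit <- TRUE
    off <- val_off + as.integer(len)
  }
  get_us <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    dcm_u16(v, 1L)
  }
  get_str <- function(key, default = NULL) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    trim_dcm_str(v)
  }
  rows <- get_us("0028,0010")
  cols <- get_us("0028,0011")
  if (is.null(rows) || is.null(cols))
    stop("load_image: DICOM is missing Rows/Columns")
  spp <- get_us("0028,0002", 1L)
  if (spp != 1L)
    stop("load_image: multi-sample (color) DICOM is unsupported")
  nframes <- get_str("0028,0008", "1")
  if (as.integer(nframes) != 1L)
    stop("load_image: multi-frame DICOM is unsupported")
  bits <- get_us("0028,0100", 16L)
  if (!bits %in% c(8L, 16L))
    stop("load_image: only 8- or 16-bit DICOM pixel data is supported")
  pixrep <- get_us("0028,0103", 0L)
  slope <- as.numeric(get_str("0028,1053", "1"))
  intercept <- as.numeric(get_str("0028,1052", "0"))
  spacing <- get_str("0028,0030", "1")
  spacing <- as.numeric(strsplit(spacing, "\\\\")[[1]][1])
  if (!is.finite(spacing) || spacing <= 0) spacing <- 1.0
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("load_image: DICOM has no PixelData")
  npix <- rows * cols
  if (length(pd) < npix * (bits / 8L))
    stop("load_image: truncated DICOM PixelData")
  vals <- if (bits == 16L) {
    readBin(pd, "integer", n = npix, size = 2L,
            signed = (pixrep == 1L), endian = "little")
  } else {
    readBin(pd, "integer", n = npix, size = 1L,
            signed = (pixrep == 1L))
  }
  if (bits == 16L && pixrep == 0L) vals <- ifelse(vals < 0, vals + 65536, vals)
  if (bits == 8L && pixrep == 0L) vals <- ifelse(vals < 0, vals + 256, vals)
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  px <- pmax(px * slope + intercept, 0)  # clamp: MR magnitudes are >= 0
  image2d(px, pixel_spacing = spacing)
}

trim_dcm_str <- function(v) {
  s <- rawToChar(v[v != as.raw(0)])
  gsub("^\\s+|\\s+$", "", s)
}

#' Write a segmentation result record as JSON
#'
#' @param result a [segmentation_result()].
#' @param roi optional [circle_roi()]; its circle is embedded as
#'   `[center_row, center_col, radius]`.
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
write_result_json <- function(result, roi = NULL, path) {
  rec <- list(method = result$method_name,
              dice = if (is.na(result$dice)) NULL else result$dice,
              iterations = result$iterations_run,
              foreground_pixels = sum(result$mask$pixels))
  if (!is.null(roi))
    rec$circle <- c(roi$center[1], roi$center[2], roi$radius)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
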