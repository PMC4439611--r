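# Minimal explicit-VR little-endian DICOM writer for test fixtures.
# Writes a single-frame grayscale image with the Image Pixel module tags
# the package reader consumes.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                    endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) value_raw <- c(value_raw, as.raw(0))
  head <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

dcm_str <- function(s) charToRaw(s)

write_test_dicom <- function(path, pixels, bits = 16L,
                             slope = NULL, intercept = NULL,
                             n_frames = NULL, samples_per_pixel = NULL,
                             pixel_spacing = NULL) {
  stopifnot(is.matrix(pixels))
  rows <- nrow(pixels); cols <- ncol(pixels)
  # pixel data row-major, unsigned little-endian
  vals <- as.integer(t(pixels))
  pd <- if (bits == 16L) {
    writeBin(ifelse(vals > 32767L, vals - 65536L, vals), raw(),
             size = 2L, endian = "little")
  } else as.raw(vals)
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1")))
  body <- c(
    dcm_element(0x0028, 0x0002, "US",
                dcm_raw_u16(samples_per_pixel %||% 1L)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str("MONOCHROME2")))
  if (!is.null(n_frames))
    body <- c(body, dcm_element(0x0028, 0x0008, "IS",
                                dcm_str(as.character(n_frames))))
  body <- c(body,
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(cols)))
  if (!is.null(pixel_spacing))
    body <- c(body, dcm_element(0x0028, 0x0030, "DS",
                                dcm_str(sprintf("%g\\%g", pixel_spacing,
                                                pixel_spacing))))
  body <- c(body,
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(bits)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(0L)))
  if (!is.null(intercept))
    body <- c(body, dcm_element(0x0028, 0x1052, "DS",
                                dcm_str(as.character(intercept))))
  if (!is.null(slope))
    body <- c(body, dcm_element(0x0028, 0x1053, "DS",
                                dcm_str(as.character(slope))))
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", pd))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
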