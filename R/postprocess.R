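#' Detect the shoulder side of the image
#'
#' Compares the total intensity mass of the left and right image halves
#' (the histogram mass is concentrated on the side holding the shoulder);
#' the heavier half is the shoulder side. The scapula suppression sector —
#' a 90 degree angular interval on the ROI circle — points from the ROI
#' center toward that side's image border, because the scapula lies on the
#' same side as the shoulder, at the periphery of the circle.
#'
#' @param image an [image2d()].
#' @param sector_deg angular width of the scapula sector in degrees
#'   (default 90, must be in (0, 180]).
#' @return list of class `side_info` with `side` (`"left"`/`"right"`),
#'   `sector_center` (radians, `atan2(drow, dcol)` convention: `pi` points
#'   left, `0` right), `sector_halfwidth` (radians).
#' @export
detect_side <- function(image, sector_deg = 90) {
  stopifnot(sector_deg > 0, sector_deg <= 180)
  I <- as_pixels(image)
  half <- ncol(I) %/% 2
  left_mass <- sum(I[, seq_len(half)])
  right_mass <- sum(I[, (ncol(I) - half + 1L):ncol(I)])
  if (left_mass == right_mass) {
    warning("detect_side: exact left/right tie; defaulting to right")
    side <- "right"
  } else side <- if (left_mass > right_mass) "left" else "right"
  structure(list(side = side,
                 sector_center = if (side == "left") pi else 0,
                 sector_halfwidth = sector_deg / 2 * pi / 180),
            class = "side_info")
}

#' Remove scapula / tendon attachments from a raw segmentation
#'
#' Reconstruction of the anatomical cleanup: (a) within the outer annulus
#' `[0.8, 1.0] * enlarged_radius` of the ROI restricted to the scapula
#' sector, the mask is eroded with a disk structuring element, cutting the
#' thin bridges that connect the head to the scapula arc or tendon bands;
#' (b) connected components are labeled; (c) the component with maximal
#' overlap with the (shrunken, `0.9 * radius`) Hough disk is kept — more
#' robust than keeping the largest component when the scapula fragment is
#' big; (d) the kept component is dilated with the same element,
#' intersected with the original mask, to restore the eroded true boundary
#' (a morphological opening restricted to the sector).
#'
#' @param mask a [binary_mask()] (raw segmentation).
#' @param roi the [circle_roi()] the segmentation ran in.
#' @param side a `side_info` from [detect_side()].
#' @param element_radius disk structuring-element radius in pixels
#'   (default 4): the smallest disk that disconnects the partial-volume
#'   bridges left across a blurred joint space after thresholding.
#' @return cleaned [binary_mask()]. If erosion empties the mask, the
#'   largest pre-erosion component is returned with a warning.
#' @export
suppress_attachments <- function(mask, roi, side, element_radius = 4L) {
  m <- as_pixels(mask)
  if (sum(m) == 0L) {
    warning("suppress_attachments: empty input mask")
    return(binary_mask(m))
  }
  nr <- nrow(m); nc <- ncol(m)
  d <- dist_from(nr, nc, roi$center)
  ang <- angle_about(nr, nc, roi$center)
  sector <- d >= 0.8 * roi$enlarged_radius & d <= roi$enlarged_radius &
    ang_diff(ang, side$sector_center) <= side$sector_halfwidth
  brush <- EBImage::makeBrush(2L * element_radius + 1L, shape = "disc")
  eroded <- EBImage::erode(m, brush)
  m2 <- m
  m2[sector] <- eroded[sector]
  lab <- EBImage::bwlabel(m2)
  nlab <- max(lab)
  if (nlab == 0L) {
    warning("suppress_attachments: erosion removed everything; ",
            "falling back to the largest pre-erosion component")
    lab0 <- EBImage::bwlabel(m)
    keep <- which.max(tabulate(lab0[lab0 > 0]))
    return(binary_mask(lab0 == keep))
  }
  target <- d <= 0.9 * roi$radius
  overlap <- vapply(seq_len(nlab), function(l) sum(lab == l & target),
                    numeric(1))
  if (max(overlap) == 0) {
    keep <- which.max(tabulate(lab[lab > 0]))
  } else keep <- which.max(overlap)
  kept <- (lab == keep) + 0
  restored <- EBImage::dilate(kept, brush) * m
  binary_mask(restored > 0)
}

#' Fill interior holes of a mask
#'
#' Every background region not connected to the image border becomes
#' foreground (flood-fill hole filling) — this is what absorbs the
#' "white pixel" holes that bone edema leaves inside the segmented head.
#' Monotone (never removes pixels) and idempotent.
#'
#' @param mask a [binary_mask()].
#' @return filled [binary_mask()].
#' @export
fill_holes <- function(mask) {
  m <- as_pixels(mask)
  binary_mask(EBImage::fillHull(m) > 0)
}

#' Extract the ordered outer boundary of a mask
#'
#' Traces the outer boundary of the largest connected component as a
#' closed polygon of (row, col) pixels (Moore neighborhood tracing); the
#' boundary pixels are mask pixels with at least one 4-neighbor outside.
#'
#' @param mask a [binary_mask()] with at least one foreground pixel.
#' @return integer matrix with columns `row`, `col` in boundary order.
#' @export
extract_boundary <- function(mask) {
  m <- as_pixels(mask)
  if (sum(m) == 0L) stop("extract_boundary: empty mask")
  lab <- EBImage::bwlabel(m)
  keep <- which.max(tabulate(lab[lab > 0]))
  comp <- (lab == keep) + 0
  oc <- EBImage::ocontour(comp)[[1]]
  # EBImage returns 0-based (dim1, dim2) coordinates
  out <- cbind(row = oc[, 1] + 1L, col = oc[, 2] + 1L)
  storage.mode(out) <- "integer"
  out
}

#' Full anatomical postprocessing
#'
#' [suppress_attachments()] then [fill_holes()], returning an updated
#' [segmentation_result()] with a re-extracted boundary.
#'
#' @param result a [segmentation_result()].
#' @param roi the [circle_roi()].
#' @param side a `side_info` from [detect_side()].
#' @param element_radius disk element radius (default 4).
#' @return updated [segmentation_result()].
#' @export
postprocess_result <- function(result, roi, side, element_radius = 4L) {
  cleaned <- suppress_attachments(result$mask, roi, side, element_radius)
  filled <- fill_holes(cleaned)
  bnd <- if (sum(filled$pixels) > 0) extract_boundary(filled) else NULL
  segmentation_result(filled, bnd, result$method_name,
                      result$iterations_run, result$dice)
}

#' Red-boundary overlay of a segmentation on its image
#'
#' Writes an RGB PNG with the traced boundary drawn in red over the
#' (rescaled) grayscale image.
#'
#' @param image [image2d()].
#' @param boundary boundary matrix from [extract_boundary()].
#' @param path output PNG path.
#' @return `invisible(path)`.
#' @export
save_overlay <- function(image, boundary, path) {
  I <- as_pixels(image)
  g <- (I - min(I)) / max(diff(range(I)), 1e-12)
  rgb <- array(rep(g, 3L), dim = c(nrow(I), ncol(I), 3L))
  if (!is.null(boundary) && nrow(boundary) > 0) {
    lin <- (boundary[, 2] - 1L) * nrow(I) + boundary[, 1]
    rgb[lin] <- 1                        # red channel
    rgb[lin + length(I)] <- 0            # green
    rgb[lin + 2L * length(I)] <- 0       # blue
  }
  png::writePNG(rgb, path)
  invisible(path)
}
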