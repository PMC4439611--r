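#' Circular region of interest
#'
#' Holds the circle found by the circular Hough transform plus the
#' enlarged working radius that defines the ROI disk. The enlargement
#' absorbs the non-circular parts of the humeral head (the head is only
#' quasi-circular, and lesions deform it).
#'
#' @param center numeric `(row, col)` in pixels.
#' @param radius detected circle radius in pixels (> 0).
#' @param shape `(rows, cols)` of the image the ROI lives on.
#' @param enlargement_factor ratio `enlarged_radius / radius` (default 1.2).
#' @return object of class `circle_roi` with fields `center`, `radius`,
#'   `enlarged_radius`, `roi_mask` (a [binary_mask()] disk clipped to the
#'   image bounds), and `score` (Hough support fraction, if known).
#' @export
circle_roi <- function(center, radius, shape, enlargement_factor = 1.2) {
  if (radius <= 0) stop("circle_roi: radius must be > 0")
  if (enlargement_factor < 1) stop("circle_roi: enlargement factor must be >= 1")
  enlarged <- enlargement_factor * radius
  d <- dist_from(shape[1], shape[2], center)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 enlarged_radius = enlarged,
                 roi_mask = binary_mask(d <= enlarged),
                 score = NA_real_),
            class = "circle_roi")
}

#' @export
print.circle_roi <- function(x, ...) {
  cat(sprintf("circle_roi: center (%.1f, %.1f), radius %.1f px, ROI radius %.1f px\n",
              x$center[1], x$center[2], x$radius, x$enlarged_radius))
  invisible(x)
}

# ---- Canny edge detection --------------------------------------------------
# Gaussian smoothing, Sobel gradients, non-maximum suppression along the
# quantized gradient direction, and hysteresis thresholding (thresholds
# relative to the maximum gradient magnitude).
canny_edges <- function(I, sigma = 1.4, low = 0.10, high = 0.20) {
  S <- gaussian_smooth(I, sigma)
  gx <- shift_e(S) - shift_w(S)           # column direction
  gy <- shift_s(S) - shift_n(S)           # row direction
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 0) return(matrix(FALSE, nrow(I), ncol(I)))
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)  # 0: E-W, 1: NE-SW, 2: N-S, 3: NW-SE
  nmax <- mag
  nbr <- function(m, dr, dc) {
    out <- m
    if (dr == -1) out <- shift_n(out) else if (dr == 1) out <- shift_s(out)
    if (dc == -1) out <- shift_w(out) else if (dc == 1) out <- shift_e(out)
    out
  }
  keep <- (sector == 0 & mag >= nbr(mag, 0, 1) & mag >= nbr(mag, 0, -1)) |
          (sector == 1 & mag >= nbr(mag, 1, 1) & mag >= nbr(mag, -1, -1)) |
          (sector == 2 & mag >= nbr(mag, 1, 0) & mag >= nbr(mag, -1, 0)) |
          (sector == 3 & mag >= nbr(mag, 1, -1) & mag >= nbr(mag, -1, 1))
  nmax[!keep] <- 0
  strong <- nmax >= high * max(mag)
  weak <- nmax >= low * max(mag)
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep_labels <- unique(lab[strong])
  weak & (lab %in% keep_labels) & matrix(TRUE, nrow(I), ncol(I))
}

#' Detect the humeral head as a circle
#'
#' Builds a Canny edge map, then votes each edge pixel into a circular
#' Hough accumulator over candidate radii. The peak of the perimeter-
#' normalized accumulator gives the circle; ties are broken
#' deterministically (largest radius, then smallest row, then smallest
#' column). The Hough transform tolerates boundary gaps, so heads deformed
#' by edema or a Hill-Sachs notch are still found.
#'
#' @param image an [image2d()] (ideally preprocessed).
#' @param r_min,r_max radius search range in pixels; defaults are 0.1 and
#'   0.4 of the smaller image dimension.
#' @param enlargement_factor working-ROI enlargement (default 1.2).
#' @param min_support minimum fraction of the circle perimeter that must be
#'   supported by edge votes (default 0.25); below it detection fails.
#' @return a [circle_roi()].
#' @export
detect_humeral_circle <- function(image, r_min = NULL, r_max = NULL,
                                  enlargement_factor = 1.2,
                                  min_support = 0.25) {
  I <- as_pixels(image)
  nr <- nrow(I); nc <- ncol(I)
  if (is.null(r_min)) r_min <- max(2L, round(0.1 * min(nr, nc)))
  if (is.null(r_max)) r_max <- round(0.4 * min(nr, nc))
  if (!(r_min >= 2 && r_min < r_max && r_max <= min(nr, nc) / 2))
    stop("detect_humeral_circle: need 2 <= r_min < r_max <= min(H,W)/2")
  edges <- canny_edges(I)
  ep <- which(edges, arr.ind = TRUE)
  if (nrow(ep) == 0L)
    stop("detect_humeral_circle: no edges found (blank image?)")
  best <- NULL
  for (r in seq(r_min, r_max)) {
    n_ang <- max(48L, ceiling(pi * r))
    th <- seq(0, 2 * pi, length.out = n_ang + 1L)[-(n_ang + 1L)]
    cr <- round(rep(ep[, 1], times = n_ang) -
                  rep(r * sin(th), each = nrow(ep)))
    cc <- round(rep(ep[, 2], times = n_ang) -
                  rep(r * cos(th), each = nrow(ep)))
    ok <- cr >= 1L & cr <= nr & cc >= 1L & cc <= nc
    votes <- tabulate((cc[ok] - 1L) * nr + cr[ok], nbins = nr * nc)
    peak <- which.max(votes)
    score <- votes[peak] / n_ang
    cand <- list(score = score, r = r,
                 row = ((peak - 1L) %% nr) + 1L,
                 col = ((peak - 1L) %/% nr) + 1L)
    if (is.null(best) || better_peak(cand, best)) best <- cand
  }
  if (best$score < min_support)
    stop("detect_humeral_circle: no circle with sufficient support ",
         sprintf("(best %.2f < %.2f)", best$score, min_support))
  roi <- circle_roi(c(best$row, best$col), best$r, c(nr, nc),
                    enlargement_factor)
  roi$score <- best$score
  roi
}

# deterministic tie-break: score, then largest radius, smallest row/col
better_peak <- function(a, b, tol = 1e-9) {
  if (a$score > b$score + tol) return(TRUE)
  if (a$score < b$score - tol) return(FALSE)
  if (a$r != b$r) return(a$r > b$r)
  if (a$row != b$row) return(a$row < b$row)
  a$col < b$col
}

#' Initial level-set field inside the ROI
#'
#' Signed distance to a circle concentric with the detected one at half
#' its radius, positive inside (the inside-positive sign convention used
#' by both level-set engines). Starting strictly inside the bone suits the
#' global ACWE model and satisfies the SPF model's requirement that the
#' initial contour intersect or surround the target boundary.
#'
#' @param roi a [circle_roi()].
#' @param shape `(rows, cols)` of the target grid.
#' @param epsilon Heaviside/Dirac regularization width stored with the
#'   field (default 1.5).
#' @return list of class `level_set_field` with fields `phi`, `epsilon`.
#' @export
initial_level_set <- function(roi, shape, epsilon = 1.5) {
  r0 <- 0.5 * roi$radius
  phi <- r0 - dist_from(shape[1], shape[2], roi$center)
  structure(list(phi = phi, epsilon = epsilon), class = "level_set_field")
}
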