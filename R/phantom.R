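#' Synthetic shoulder-phantom specification
#'
#' Describes a synthetic axial shoulder slice: a bright quasi-circular
#' humeral head on dark background, an adjacent scapula arc and tendon
#' band of similar intensity, optionally a hyperintense edema blob inside
#' the head (edematous group) or a cortical notch carved from the head
#' (Hill-Sachs group), all multiplied by a smooth low-frequency bias field
#' and corrupted with Rician noise. Defaults model the study conditions:
#' 256 x 256 pixels, head radius 40 px, head/background intensity 200/40
#' (head markedly brighter than background, with scapula and tendon close
#' to head intensity as on PD-weighted slices).
#'
#' @param size image `(rows, cols)` (default `c(256, 256)`).
#' @param side `"left"` or `"right"`: which image half the shoulder
#'   occupies.
#' @param head_center `(row, col)`; default centers the head vertically and
#'   shifts it toward `side`.
#' @param head_radius head disk radius in pixels.
#' @param head_intensity,background_intensity MR units.
#' @param edema `NULL` or list `(offset = c(drow, dcol), radius,
#'   multiplier)`: hyperintense blob inside the head (part of the true
#'   head).
#' @param notch `NULL` or list `(position, depth_frac, arc_frac)`:
#'   Hill-Sachs compression — pixels of the head with radius above
#'   `(1 - depth_frac) * head_radius` and angle within
#'   `position +/- arc_frac * pi` are carved out of both image and truth.
#' @param scapula `NULL` or list `(arc_radius, gap, thickness, span,
#'   intensity, bridge_width)`: the scapular/glenoid edge, modeled as an
#'   arc of its own circle (radius `arc_radius >= head_radius + gap`)
#'   positioned so the arc is concave toward the head — congruent with
#'   it, as the glenoid is — and separated from the head surface by
#'   `gap` pixels of joint space at the closest (shoulder-side) azimuth;
#'   `span` (degrees) is the arc extent on its own circle and `thickness`
#'   grows outward. `bridge_width > 0` draws a bright tissue bridge of
#'   that width across the joint space at the tangent azimuth, producing
#'   the narrow head-scapula attachment that postprocessing is designed
#'   to cut.
#' @param tendon `NULL` or list `(width, intensity)`: band of soft tissue
#'   running from the head to the shoulder-side border.
#' @param transition_sigma Gaussian width (pixels) of the smooth
#'   transition zone between structures (default 2): PD-weighted slices
#'   have soft bone/soft-tissue transitions rather than step edges, and
#'   this is the property that makes their segmentation hard. Set 0 for
#'   ideal step edges.
#' @param bias_amplitude multiplicative bias amplitude in `[0, 1)`; the
#'   field is `1 + amplitude * s` with `s` a normalized sum of two seeded
#'   low-frequency cosine modes.
#' @param noise_sigma Rician noise scale (MR units);
#'   `out = sqrt((clean + s*g1)^2 + (s*g2)^2)` with standard normal g1, g2.
#' @param seed integer seed controlling bias phases and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L), side = "left",
                         head_center = NULL, head_radius = 40,
                         head_intensity = 200, background_intensity = 40,
                         edema = NULL, notch = NULL,
                         scapula = list(arc_radius = 60, gap = 4,
                                        thickness = 6, span = 90,
                                        intensity = 190, bridge_width = 0),
                         tendon = list(width = 6, intensity = 170),
                         transition_sigma = 2, bias_amplitude = 0,
                         noise_sigma = 0, seed = 1L) {
  if (is.null(head_center)) {
    off <- round(0.07 * size[2])
    head_center <- c(round(size[1] / 2),
                     round(size[2] / 2) + if (side == "left") -off else off)
  }
  if (!side %in% c("left", "right")) stop("phantom_spec: side must be left/right")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("phantom_spec: bias_amplitude must lie in [0, 1)")
  if (head_intensity <= 0 || background_intensity <= 0)
    stop("phantom_spec: intensities must be positive")
  if (head_center[1] - head_radius < 1 || head_center[1] + head_radius > size[1] ||
      head_center[2] - head_radius < 1 || head_center[2] + head_radius > size[2])
    stop("phantom_spec: head must lie fully inside the image")
  structure(list(size = as.integer(size), side = side,
                 head_center = head_center, head_radius = head_radius,
                 head_intensity = head_intensity,
                 background_intensity = background_intensity,
                 edema = edema, notch = notch, scapula = scapula,
                 tendon = tendon, transition_sigma = transition_sigma,
                 bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic shoulder slice with ground truth
#'
#' Renders the clean scene described by a [phantom_spec()], multiplies it
#' by the smooth bias field, and applies Rician corruption. The truth mask
#' is the head disk including any edema and excluding any notch.
#' Bit-identical for identical specs (seed included).
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` ([image2d()]), `truth` ([binary_mask()]),
#'   `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(noise_sigma = 10, seed = 7))
#' ph$image
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$size[1]; nc <- spec$size[2]
  d <- dist_from(nr, nc, spec$head_center)
  ang <- angle_about(nr, nc, spec$head_center)
  clean <- matrix(spec$background_intensity, nr, nc)
  head <- d <= spec$head_radius
  clean[head] <- spec$head_intensity
  truth <- head

  if (!is.null(spec$edema)) {
    ec <- spec$head_center + spec$edema$offset
    eb <- dist_from(nr, nc, ec) <= spec$edema$radius & head
    clean[eb] <- spec$edema$multiplier * spec$head_intensity
  }
  if (!is.null(spec$notch)) {
    carved <- head & d >= (1 - spec$notch$depth_frac) * spec$head_radius &
      ang_diff(ang, spec$notch$position) <= spec$notch$arc_frac * pi
    clean[carved] <- spec$background_intensity
    truth <- truth & !carved
  }
  side_ang <- if (spec$side == "left") pi else 0
  if (!is.null(spec$scapula)) {
    sc <- spec$scapula
    rs <- if (is.null(sc$arc_radius)) 60 else sc$arc_radius
    if (rs < spec$head_radius + sc$gap)
      stop("make_phantom: scapula arc_radius must be >= head_radius + gap")
    u <- if (spec$side == "left") c(0, -1) else c(0, 1)
    sc_center <- spec$head_center - (rs - spec$head_radius - sc$gap) * u
    ds <- dist_from(nr, nc, sc_center)
    ang_s <- angle_about(nr, nc, sc_center)
    face <- atan2(u[1], u[2])  # tangent azimuth, seen from the arc center
    arc <- ds >= rs & ds <= rs + sc$thickness &
      ang_diff(ang_s, face) <= sc$span / 2 * pi / 180
    clean[arc & !truth] <- sc$intensity
    bw <- if (is.null(sc$bridge_width)) 0 else sc$bridge_width
    if (bw > 0) {
      rr <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      along <- abs(rr - spec$head_center[1]) <= bw / 2 &
        (if (spec$side == "left")
           cc <= spec$head_center[2] & cc >= spec$head_center[2] -
             (spec$head_radius + sc$gap + 1)
         else
           cc >= spec$head_center[2] & cc <= spec$head_center[2] +
             (spec$head_radius + sc$gap + 1))
      clean[along & !truth & !arc] <- sc$intensity
    }
  }
  if (!is.null(spec$tendon)) {
    td <- spec$tendon
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    # anterior band reaching the shoulder-side border; sits at the ROI
    # periphery in the same direction as the shoulder side
    row0 <- spec$head_center[1] - round(0.5 * spec$head_radius)
    band <- abs(rr - row0) <= td$width / 2 &
      (if (spec$side == "left") cc <= spec$head_center[2]
       else cc >= spec$head_center[2])
    clean[band & !truth & d > spec$head_radius] <- td$intensity
  }

  if (!is.null(spec$transition_sigma) && spec$transition_sigma > 0)
    clean <- gaussian_smooth(clean, spec$transition_sigma)
  out <- with_seed(spec$seed, {
    img <- clean
    if (spec$bias_amplitude > 0) {
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      rrn <- matrix(seq_len(nr) / nr, nr, nc)
      ccn <- matrix(seq_len(nc) / nc, nr, nc, byrow = TRUE)
      s <- cos(pi * rrn + ph1) + cos(pi * ccn + ph2)
      s <- s / max(abs(s))
      img <- img * (1 + spec$bias_amplitude * s)
    }
    if (spec$noise_sigma > 0) {
      g1 <- matrix(stats::rnorm(nr * nc), nr, nc)
      g2 <- matrix(stats::rnorm(nr * nc), nr, nc)
      img <- sqrt((img + spec$noise_sigma * g1)^2 + (spec$noise_sigma * g2)^2)
    }
    img
  })
  list(image = image2d(out), truth = binary_mask(truth), spec = spec)
}

#' Generate a seeded phantom cohort
#'
#' Draws `n_normal + n_edema + n_notch` phantoms with per-case parameter
#' jitter (head radius +/-15%, intensities +/-10%, random edema size and
#' orientation, random notch orientation), all under the study's standard
#' corruption (bias amplitude 0.3, Rician sigma 10% of the head
#' intensity). Edema blobs are placed peripherally — post-traumatic bone
#' edema typically sits near the cortex, where its hyperintensity blurs
#' the bone border and makes the edematous group harder to segment.
#' Deterministic for a fixed seed.
#'
#' @param n_normal,n_edema,n_notch group sizes (>= 0).
#' @param seed cohort seed.
#' @param size image size.
#' @return list of cases, each `(image, truth, group, spec)`.
#' @export
make_cohort <- function(n_normal, n_edema, n_notch, seed = 1L,
                        size = c(256L, 256L)) {
  groups <- rep(c("normal", "edema", "hill_sachs"),
                times = c(n_normal, n_edema, n_notch))
  n <- length(groups)
  if (n == 0L) return(list())
  draws <- with_seed(seed, {
    lapply(seq_len(n), function(i)
      list(radius_jit = stats::runif(1, 0.85, 1.15),
           head_jit = stats::runif(1, 0.9, 1.1),
           bg_jit = stats::runif(1, 0.9, 1.1),
           side = sample(c("left", "right"), 1),
           edema_r = stats::runif(1, 0.25, 0.4),
           edema_ang = stats::runif(1, 0, 2 * pi),
           edema_off = stats::runif(1, 0.55, 0.85),
           edema_mult = stats::runif(1, 1.4, 1.6),
           notch_ang = stats::runif(1, 0, 2 * pi),
           notch_depth = stats::runif(1, 0.2, 0.3),
           case_seed = sample.int(.Machine$integer.max %/% 2L, 1)))
  })
  lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    g <- groups[i]
    hr <- 40 * dr$radius_jit
    hi <- 200 * dr$head_jit
    edema <- if (g == "edema") {
      er <- dr$edema_r * hr
      off_len <- dr$edema_off * (hr - er)
      list(offset = off_len * c(sin(dr$edema_ang), cos(dr$edema_ang)),
           radius = er, multiplier = dr$edema_mult)
    }
    notch <- if (g == "hill_sachs")
      list(position = dr$notch_ang, depth_frac = dr$notch_depth,
           arc_frac = 0.125)
    spec <- phantom_spec(size = size, side = dr$side, head_radius = hr,
                         head_intensity = hi,
                         background_intensity = 40 * dr$bg_jit,
                         edema = edema, notch = notch,
                         bias_amplitude = 0.3, noise_sigma = 0.10 * hi,
                         seed = dr$case_seed)
    ph <- make_phantom(spec)
    list(image = ph$image, truth = ph$truth, group = g, spec = spec)
  })
}
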