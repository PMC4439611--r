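#' Homomorphic bias-field correction
#'
#' Models each pixel as the product of a smooth low-frequency illumination
#' (bias) field and a high-frequency reflectance (tissue) component,
#' `f = i * r`. Taking logs turns the product into a sum, so a frequency-
#' domain high-emphasis filter can attenuate the illumination while keeping
#' the tissue contrast:
#' `out = exp( IFFT( FFT(ln(f + 1)) * H ) ) - 1`, with the Gaussian
#' high-pass emphasis
#' `H(u,v) = gain_low + (gain_high - gain_low) * (1 - exp(-D^2 / (2 s^2)))`
#' where `D` is the distance from the zero-frequency origin in cycles per
#' image and `s = cutoff_sigma`. The `+1` offset avoids `log(0)` on empty
#' background; the DC component passes at `gain_high` so overall brightness
#' is preserved; output is clamped at 0.
#'
#' The default cutoff places the notch at the scale on which scanner bias
#' fields vary — a fraction of the field of view (below ~1 cycle per
#' image) — while anatomy the size of the humeral head (about a third of
#' the image, hence >= 3 cycles) passes nearly untouched; a wider notch
#' would high-pass the bone itself and ring inside it.
#'
#' @param cutoff_sigma Gaussian width of the emphasis transition in cycles
#'   per image (default 0.6).
#' @param gain_high multiplier for high frequencies (default 1).
#' @param gain_low multiplier for the lowest non-DC frequencies (default
#'   0.25): attenuates rather than erases illumination, preserving some
#'   low-frequency bone/background contrast for the segmentation models.
#' @return an object of class `homomorphic_params`.
#' @export
homomorphic_params <- function(cutoff_sigma = 0.6, gain_high = 1.0,
                               gain_low = 0.25) {
  if (cutoff_sigma <= 0) stop("homomorphic_params: cutoff_sigma must be > 0")
  if (!(gain_high >= gain_low && gain_low >= 0))
    stop("homomorphic_params: need gain_high >= gain_low >= 0")
  structure(list(cutoff_sigma = cutoff_sigma, gain_high = gain_high,
                 gain_low = gain_low),
            class = "homomorphic_params")
}

#' @rdname homomorphic_params
#' @param image an [image2d()] with finite non-negative intensities.
#' @param params a [homomorphic_params()].
#' @return `homomorphic_correct()` returns the corrected [image2d()].
#' @examples
#' img <- image2d(matrix(runif(64 * 64, 50, 150), 64, 64))
#' flat <- homomorphic_correct(img, homomorphic_params())
#' @export
homomorphic_correct <- function(image, params = homomorphic_params()) {
  stopifnot(inherits(image, "image2d"))
  f <- image$pixels
  if (any(!is.finite(f))) stop("homomorphic_correct: non-finite input")
  g <- log(f + 1)
  # mirror padding removes the wrap-around discontinuity the DFT would
  # otherwise see, so the bias stays concentrated at the lowest frequencies
  nr <- nrow(g); nc <- ncol(g)
  gp <- g[c(seq_len(nr), rev(seq_len(nr))), c(seq_len(nc), rev(seq_len(nc)))]
  G <- stats::fft(gp)
  H <- gaussian_emphasis(2L * nr, 2L * nc, params, fscale = 0.5)
  H[1, 1] <- params$gain_high  # DC passes: keep mean log-brightness
  g_f <- Re(stats::fft(G * H, inverse = TRUE)) / length(gp)
  out <- pmax(exp(g_f[seq_len(nr), seq_len(nc)]) - 1, 0)
  image2d(out, pixel_spacing = image$pixel_spacing)
}

# frequency response on the unshifted FFT grid; D in cycles per (original)
# image, so on a mirror-padded grid fscale = 0.5 maps bins back to that unit
gaussian_emphasis <- function(nr, nc, params, fscale = 1) {
  fr <- fscale * c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))[seq_len(nr)]
  fc <- fscale * c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))[seq_len(nc)]
  D2 <- outer(fr^2, fc^2, "+")
  params$gain_low + (params$gain_high - params$gain_low) *
    (1 - exp(-D2 / (2 * params$cutoff_sigma^2)))
}
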