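# Shared phantom builders for the test suite. All deterministic via seeds.

# bare head only: no scapula, no tendon; optional blur/noise/bias
bare_phantom <- function(seed = 1L, noise_sigma = 0, bias_amplitude = 0,
                         transition_sigma = 2, head_radius = 40, ...) {
  make_phantom(phantom_spec(scapula = NULL, tendon = NULL,
                            head_radius = head_radius,
                            transition_sigma = transition_sigma,
                            noise_sigma = noise_sigma,
                            bias_amplitude = bias_amplitude,
                            seed = seed, ...))
}

# the standard corruption: Rician sigma = 10% of head intensity, bias 0.3
standard_phantom <- function(seed = 11L, ...) {
  make_phantom(phantom_spec(noise_sigma = 20, bias_amplitude = 0.3,
                            seed = seed, ...))
}

# multiplicative-bias phantom: clean two-level scene (step edges) times a
# smooth half-cosine illumination ramp spanning 0.6..1.4 across the columns
bias_ramp_phantom <- function(seed = 1L) {
  ph <- bare_phantom(seed = seed, transition_sigma = 0)
  px <- as.matrix(ph$image)
  nc <- ncol(px)
  ramp <- matrix(1 + 0.4 * cos(pi * (seq_len(nc) - 1) / (nc - 1)),
                 nrow(px), nc, byrow = TRUE)
  list(image = image2d(px * ramp), truth = ph$truth, illum = ramp)
}

# standard corruption plus scapula attached through a capsule bridge and a
# wide tendon band: the attachment-removal study condition
touching_phantom <- function(seed) {
  make_phantom(phantom_spec(
    scapula = list(arc_radius = 60, gap = 4, thickness = 6, span = 90,
                   intensity = 190, bridge_width = 2),
    tendon = list(width = 8, intensity = 170),
    noise_sigma = 20, bias_amplitude = 0.3, seed = seed))
}

cv_inside <- function(img, mask) {
  v <- as.matrix(img)[as.matrix(mask) == 1]
  stats::sd(v) / mean(v)
}
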