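# Internal grid helpers shared by the PDE solvers.
#
# Convention everywhere: matrices are indexed [row, col], 1-based in R;
# "north" is row - 1, "west" is col - 1. Border handling is replicate
# (zero-flux / Neumann), matching the boundary condition of the diffusion
# and level-set schemes.

shift_n <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_s <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_w <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_e <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# central differences with replicate borders
grad_central <- function(m) {
  list(dr = (shift_s(m) - shift_n(m)) / 2,
       dc = (shift_e(m) - shift_w(m)) / 2)
}

laplacian4 <- function(m) {
  shift_n(m) + shift_s(m) + shift_e(m) + shift_w(m) - 4 * m
}

# separable Gaussian smoothing with replicate padding; kernel_size must be odd
gaussian_smooth <- function(m, sigma, kernel_size = NULL) {
  if (is.null(kernel_size)) {
    kernel_size <- 2L * ceiling(3 * sigma) + 1L
  }
  stopifnot(kernel_size %% 2L == 1L, kernel_size >= 1L, sigma > 0)
  half <- (kernel_size - 1L) %/% 2L
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(x, along_rows) {
    n <- if (along_rows) nrow(x) else ncol(x)
    idx_pad <- c(rep(1L, half), seq_len(n), rep(n, half))
    out <- 0
    for (j in seq_len(kernel_size)) {
      sel <- idx_pad[j:(j + n - 1L)]
      out <- out + k[j] * (if (along_rows) x[sel, , drop = FALSE]
                           else x[, sel, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

# Euclidean distance of every pixel from a (row, col) point
dist_from <- function(nrow, ncol, center) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  sqrt((rr - center[1])^2 + (cc - center[2])^2)
}

# angle (radians, atan2(drow, dcol) in (-pi, pi]) of every pixel about center
angle_about <- function(nrow, ncol, center) {
  rr <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  atan2(rr - center[1], cc - center[2])
}

# smallest absolute angular difference
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Otsu threshold of a numeric matrix/vector (256-bin between-class variance)
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)),
                nbins = levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[levels]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

as_pixels <- function(x) {
  if (inherits(x, "image2d") || inherits(x, "binary_mask")) x$pixels
  else if (is.matrix(x)) x
  else stop("expected an image2d, binary_mask, or matrix")
}
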