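# loop-based reference for the ICOV formula, independent of the vectorized path
icov_reference <- function(I) {
  I <- pmax(I, 1e-6)
  nr <- nrow(I); nc <- ncol(I)
  at <- function(r, c) I[min(max(r, 1L), nr), min(max(c, 1L), nc)]
  q <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dr <- (at(r + 1, c) - at(r - 1, c)) / 2
    dc <- (at(r, c + 1) - at(r, c - 1)) / 2
    lap <- at(r + 1, c) + at(r - 1, c) + at(r, c + 1) + at(r, c - 1) -
      4 * I[r, c]
    g2 <- (dr^2 + dc^2) / I[r, c]^2
    ln <- lap / I[r, c]
    num <- max(0, 0.5 * g2 - ln^2 / 16)
    q[r, c] <- sqrt(num / max((1 + ln / 4)^2, 1e-12))
  }
  q
}

test_that("ICOV vanishes on constant images and matches the loop oracle on a step edge", {
  expect_true(all(icov(matrix(7, 8, 8)) == 0))
  step <- matrix(10, 8, 8); step[, 5:8] <- 100
  q <- icov(step)
  expect_equal(q, icov_reference(step), tolerance = 1e-12)
  # maximal response on the edge columns, ~0 far from the edge
  expect_gt(max(q[, 4:5]), 10 * max(q[, c(1, 8)]))
})

test_that("ICOV is invariant to global intensity scaling", {
  set.seed(4)
  I <- matrix(runif(64, 10, 200), 8, 8)
  expect_equal(icov(I * 37), icov(I), tolerance = 1e-9)
})

test_that("speckle scale is sd/mean over the region and scale-invariant", {
  m <- binary_mask(rbind(matrix(1, 2, 8), matrix(0, 6, 8)))
  I <- matrix(5, 8, 8)
  expect_equal(estimate_speckle_scale(I, m), 0)
  # 16-pixel region of alternating 4s and 6s: mean 5, sample var 16/15
  I[1:2, ] <- c(4, 6)
  q0 <- estimate_speckle_scale(I, m)
  expect_equal(q0, sqrt(16 / 15) / 5, tolerance = 1e-12)
  expect_equal(estimate_speckle_scale(image2d(I * 3), m), q0,
               tolerance = 1e-12)
  expect_error(estimate_speckle_scale(I, binary_mask(matrix(0, 8, 8))),
               "16 pixels")
})

test_that("diffusion coefficient is 1 at q = q0, clamped in (0, 1]", {
  q <- matrix(0.3, 4, 4)
  expect_true(all(diffusion_coefficient(q, 0.3) == 1))
  # q = 0 makes the correction negative; clamp documents the cap at 1
  expect_equal(diffusion_coefficient(matrix(0, 2, 2), 0.5),
               matrix(1, 2, 2))
  # strong edges: coefficient at the floor
  expect_equal(diffusion_coefficient(matrix(1e6, 2, 2), 0.1),
               matrix(1e-8, 2, 2))
  expect_error(diffusion_coefficient(q, 0), "positive")
})

test_that("constant images are exact SRAD fixed points", {
  img <- image2d(matrix(42, 32, 32))
  out <- srad(img, srad_params(n_iters = 10))
  expect_identical(out$pixels, img$pixels)
})

test_that("variance decreases every step on a noisy homogeneous patch", {
  set.seed(9)
  I <- pmax(matrix(100 + rnorm(64 * 64, 0, 10), 64, 64), 1)
  state <- list(image = I, t = 0)
  p <- srad_params()
  vars <- numeric(21)
  vars[1] <- var(as.vector(state$image))
  for (i in 1:20) {
    state <- srad_step(state, p)
    vars[i + 1] <- var(as.vector(state$image))
  }
  expect_true(all(diff(vars) < 0))
})

test_that("SRAD preserves edges while flattening homogeneous regions", {
  set.seed(5)
  I <- matrix(50, 64, 64); I[, 33:64] <- 200
  I <- pmax(I + matrix(rnorm(64 * 64, 0, 10), 64, 64), 1)
  state <- list(image = I, t = 0)
  p <- srad_params()
  edge0 <- mean(I[, 40:60]) - mean(I[, 5:25])
  var0 <- var(as.vector(I[, 1:28]))
  for (i in 1:20) state <- srad_step(state, p)
  edge1 <- mean(state$image[, 40:60]) - mean(state$image[, 5:25])
  var1 <- var(as.vector(state$image[, 1:28]))
  expect_gte(edge1 / edge0, 0.8)
  expect_lte(var1 / var0, 0.5)
})

test_that("zero-flux boundary conserves total intensity over 50 iterations", {
  ph <- standard_phantom(seed = 31)
  total0 <- sum(ph$image$pixels)
  out <- srad(ph$image, srad_params(n_iters = 50))
  expect_lt(abs(sum(out$pixels) - total0) / total0, 0.01)
})

test_that("srad with n_iters = 0 is the identity and denoising reduces MSE", {
  ph <- bare_phantom(seed = 13, noise_sigma = 20)
  expect_identical(srad(ph$image, srad_params(n_iters = 0))$pixels,
                   ph$image$pixels)
  clean <- bare_phantom(seed = 13, noise_sigma = 0)$image$pixels
  mse0 <- mean((ph$image$pixels - clean)^2)
  out <- srad(ph$image, srad_params(n_iters = 50))
  expect_lt(mean((out$pixels - clean)^2), mse0)
})

test_that("positivity is preserved across random phantoms", {
  for (s in 1:10) {
    ph <- make_phantom(phantom_spec(noise_sigma = 15, bias_amplitude = 0.2,
                                    seed = s))
    out <- srad(ph$image, srad_params(n_iters = 10))
    expect_gte(min(out$pixels), -1e-6)
  }
})

test_that("unstable time steps are rejected up front", {
  expect_error(srad_params(dt = 0.3), "0.25")
  expect_error(srad_params(dt = 0), "0.25")
})
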