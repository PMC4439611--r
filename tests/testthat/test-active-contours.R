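# noiseless two-level disk used by several tests
disk_scene <- function(n = 128, center = c(64, 64), r = 30,
                       lo = 40, hi = 200) {
  d <- boneseg:::dist_from(n, n, center)
  I <- matrix(lo, n, n); I[d <= r] <- hi
  list(image = image2d(I), truth = binary_mask(d <= r),
       roi = circle_roi(center, r, c(n, n)))
}

test_that("regularized Heaviside identities hold to machine precision", {
  expect_identical(heaviside_reg(0), 0.5)
  phi <- seq(-50, 50, by = 0.37)
  expect_equal(heaviside_reg(phi) + heaviside_reg(-phi), rep(1, length(phi)),
               tolerance = 1e-15)
  expect_true(all(heaviside_reg(phi) > 0 & heaviside_reg(phi) < 1))
})

test_that("dirac_reg matches the numeric derivative of heaviside_reg", {
  phi <- seq(-10, 10, by = 0.05)
  h <- 1e-4
  num <- (heaviside_reg(phi + h) - heaviside_reg(phi - h)) / (2 * h)
  expect_lt(max(abs(num - dirac_reg(phi))), 1e-6)
})

test_that("region means reproduce hand-computed block means", {
  # uniform image: c1 = c2 = 9 whatever phi
  set.seed(1)
  cm <- region_means(matrix(9, 8, 8), matrix(rnorm(64), 8, 8))
  expect_equal(cm$c1, 9); expect_equal(cm$c2, 9)
  # 4x4 toy: 2x2 block of 10 on background 2, sharp phi, small epsilon
  u <- matrix(2, 4, 4); u[1:2, 1:2] <- 10
  phi <- matrix(-500, 4, 4); phi[1:2, 1:2] <- 500
  cm <- region_means(u, phi, epsilon = 0.01)
  expect_equal(cm$c1, 10, tolerance = 1e-3)
  expect_equal(cm$c2, 2, tolerance = 1e-3)
  # degenerate contour rejected
  expect_error(region_means(u, matrix(500, 4, 4), epsilon = 0.01),
               "degenerate")
})

test_that("epsilon -> 0 region means of a binary disk approach 1 and 0", {
  sc <- disk_scene(64, c(32, 32), 12, lo = 0, hi = 1)
  phi <- 12 - boneseg:::dist_from(64, 64, c(32, 32))
  cm <- region_means(sc$image$pixels, phi, epsilon = 1e-3)
  expect_equal(cm$c1, 1, tolerance = 0.05)
  expect_equal(cm$c2, 0, tolerance = 0.05)
})

test_that("ACWE segments the noiseless disk exactly and descends its energy", {
  sc <- disk_scene()
  p <- acwe_params(max_iters = 300)
  u0 <- boneseg:::normalize_roi(sc$image$pixels, sc$roi$roi_mask$pixels)
  ls <- initial_level_set(sc$roi, dim(u0), p$epsilon)
  ls$phi <- pmin(pmax(ls$phi, -3), 3)
  energy <- numeric(300)
  for (i in 1:300) {
    ls <- acwe_step(u0, ls, p, sc$roi$roi_mask$pixels)
    energy[i] <- acwe_energy(u0, ls, p, sc$roi$roi_mask$pixels)
  }
  mask <- binary_mask((ls$phi > 0) & sc$roi$roi_mask$pixels == 1)
  expect_gte(dice(mask, sc$truth), 0.99)
  expect_true(all(diff(energy) <= 1e-6 * pmax(1, abs(energy[-length(energy)]))))
})

test_that("with equal lambdas, nu = 0, and a uniform image a circle shrinks by curvature", {
  p <- acwe_params(mu = 2, nu = 0, lambda1 = 1, lambda2 = 1)
  u <- matrix(100, 128, 128)
  roi <- circle_roi(c(64, 64), 30, c(128, 128))
  ls <- initial_level_set(roi, c(128, 128))
  area0 <- sum(ls$phi > 0)
  for (i in 1:200) ls <- acwe_step(u, ls, p, NULL)
  expect_lt(sum(ls$phi > 0), area0)
})

test_that("acwe_segment: zero iterations returns the initial disk; clean phantom is recovered", {
  sc <- disk_scene()
  r0 <- acwe_segment(sc$image, sc$roi, acwe_params(max_iters = 0))
  init <- binary_mask((initial_level_set(sc$roi, dim(sc$image$pixels))$phi > 0) &
                        sc$roi$roi_mask$pixels == 1)
  expect_identical(r0$mask$pixels, init$pixels)
  ph <- bare_phantom(seed = 2)
  roi <- detect_humeral_circle(ph$image)
  expect_gte(dice(acwe_segment(ph$image, roi)$mask, ph$truth), 0.97)
})

test_that("ACWE keeps hyperintense interior edema within the segmented head", {
  ph <- make_phantom(phantom_spec(
    scapula = NULL, tendon = NULL, seed = 4,
    edema = list(offset = c(-8, 6), radius = 12, multiplier = 1.5)))
  roi <- detect_humeral_circle(ph$image)
  expect_gte(dice(acwe_segment(ph$image, roi)$mask, ph$truth), 0.90)
})

test_that("spf_function is the normalized signed distance from the mean midpoint", {
  out <- spf_function(matrix(c(0, 5, 10, 5, 5, 5, 5, 5, 5), 3, 3),
                      c1 = 10, c2 = 0)
  expect_equal(out[1, 1], -1)
  expect_equal(out[2, 1], 0)
  expect_equal(out[3, 1], 1)
  expect_true(all(out >= -1 & out <= 1))
  expect_error(spf_function(matrix(5, 3, 3), 10, 0), "degenerate")
})

test_that("SPF recovers the clean phantom within its iteration budget", {
  ph <- bare_phantom(seed = 2)
  roi <- detect_humeral_circle(ph$image)
  r <- spf_segment(ph$image, roi)
  expect_gte(dice(r$mask, ph$truth), 0.96)
  expect_lte(r$iterations_run, 120)
})

test_that("SPF is local where ACWE is global: a detached bright object in the ROI", {
  I <- matrix(40, 256, 256)
  d <- boneseg:::dist_from(256, 256, c(128, 118))
  I[d <= 35] <- 200
  blob <- boneseg:::dist_from(256, 256, c(128, 170)) <= 6
  I[blob] <- 200
  img <- image2d(boneseg:::gaussian_smooth(I, 2))
  roi <- circle_roi(c(128, 118), 35, c(256, 256), enlargement_factor = 1.7)
  acwe_cov <- sum(acwe_segment(img, roi)$mask$pixels[blob]) / sum(blob)
  spf_cov <- sum(spf_segment(img, roi)$mask$pixels[blob]) / sum(blob)
  expect_gte(acwe_cov, 0.9)   # global: captures every bright object in the ROI
  expect_lte(spf_cov, 0.05)   # local: never activated away from its contour
})

test_that("zero balloon force on a uniform image leaves the contour static", {
  img <- image2d(matrix(100, 128, 128))
  roi <- circle_roi(c(64, 64), 30, c(128, 128))
  r <- spf_segment(img, roi, spf_params(alpha = 0, max_iters = 10))
  init <- binary_mask((initial_level_set(roi, c(128, 128))$phi > 0) &
                        roi$roi_mask$pixels == 1)
  expect_gte(dice(r$mask, init), 0.98)
})

test_that("both engines are bit-deterministic", {
  ph <- standard_phantom(seed = 17)
  roi <- detect_humeral_circle(ph$image)
  expect_identical(acwe_segment(ph$image, roi)$mask$pixels,
                   acwe_segment(ph$image, roi)$mask$pixels)
  expect_identical(spf_segment(ph$image, roi)$mask$pixels,
                   spf_segment(ph$image, roi)$mask$pixels)
})
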