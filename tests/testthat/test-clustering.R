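test_that("GMM-EM recovers a two-Gaussian mixture and its log-likelihood is monotone", {
  set.seed(100)
  x <- c(rnorm(1000, 50, 10), rnorm(1000, 150, 10))
  fit <- gmm_fit(x, k = 2, seed = 1)
  means <- sort(fit$means)
  expect_lt(abs(means[1] - 50), 3)
  expect_lt(abs(means[2] - 150), 3)
  expect_true(all(abs(fit$weights - 0.5) < 0.05))
  ll <- fit$loglik_trace
  expect_true(all(diff(ll) >= -1e-8 * pmax(1, abs(ll[-length(ll)]))))
  expect_equal(rowSums(fit$posteriors), rep(1, length(x)), tolerance = 1e-9)
})

test_that("a point equidistant from two symmetric components has posterior 1/2", {
  set.seed(7)
  z <- rnorm(600, 0, 8)
  x <- c(50 + z, 150 - z, 100)  # mirror-symmetric sample; 100 is the midpoint
  fit <- gmm_fit(x, k = 2, seed = 2)
  expect_equal(fit$posteriors[length(x), 1], 0.5, tolerance = 0.01)
})

test_that("degenerate (identical) data fails after restarts", {
  expect_error(gmm_fit(rep(5, 100), k = 2, seed = 1), "degenerate")
})

test_that("GMM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(11)
  x <- c(rnorm(700, 40, 6), rnorm(1300, 180, 20))
  fit <- gmm_fit(x, k = 2, seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(max(fit$loglik_trace), mc$loglik, tolerance = 1e-4)
})

test_that("FCM converges on well-separated clusters with monotone objective", {
  x <- c(rep(10, 100), rep(200, 100))
  fit <- fcm_fit(x, c = 2, seed = 1)
  expect_equal(sort(fit$centers), c(10, 200), tolerance = 1e-3)
  J <- fit$objective_trace
  expect_true(all(diff(J) <= 1e-8 * pmax(1, J[-length(J)])))
  expect_equal(rowSums(fit$memberships), rep(1, length(x)), tolerance = 1e-9)
})

test_that("a pixel exactly at a center gets membership 1 (degenerate rule)", {
  u <- boneseg:::fcm_memberships(rbind(c(0, 25), c(9, 16)), expo = 2)
  expect_identical(u[1, ], c(1, 0))
  expect_equal(sum(u[2, ]), 1)
  expect_true(u[2, 1] > u[2, 2])  # closer center (squared distance 9) dominates
})

test_that("FCM agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  x <- c(rnorm(500, 30, 5), rnorm(500, 120, 15))
  fit <- fcm_fit(x, c = 2, m = 2, seed = 4)
  cm <- e1071::cmeans(matrix(x), centers = 2, m = 2)
  expect_equal(sort(fit$centers), sort(as.numeric(cm$centers)),
               tolerance = 0.01)
})

test_that("fixed seeds give bit-identical fits", {
  set.seed(33)
  x <- c(rnorm(300, 60, 10), rnorm(300, 160, 10))
  f1 <- gmm_fit(x, seed = 5); f2 <- gmm_fit(x, seed = 5)
  expect_identical(f1$means, f2$means)
  g1 <- fcm_fit(x, seed = 5); g2 <- fcm_fit(x, seed = 5)
  expect_identical(g1$centers, g2$centers)
})

test_that("labels_to_mask keeps the brighter cluster, lower index on ties", {
  ph <- bare_phantom(seed = 2)
  roi <- detect_humeral_circle(ph$image)
  idx <- which(roi$roi_mask$pixels == 1)
  I <- as.matrix(ph$image)
  labels <- ifelse(I[idx] > 120, 2L, 1L)  # cluster 2 is bright
  mask <- labels_to_mask(labels, roi, ph$image)
  expect_true(all(mask$pixels[idx[labels == 2L]] == 1))
  expect_true(all(mask$pixels[idx[labels == 1L]] == 0))
  expect_error(labels_to_mask(labels[-1], roi, ph$image), "per ROI pixel")
})

test_that("clustering segments the clean phantom; bias and noise degrade it", {
  ph <- bare_phantom(seed = 9, transition_sigma = 0)   # clean two-level scene
  roi <- detect_humeral_circle(ph$image)
  g0 <- dice(gmm_segment(ph$image, roi, seed = 1)$mask, ph$truth)
  f0 <- dice(fcm_segment(ph$image, roi, seed = 1)$mask, ph$truth)
  expect_gte(g0, 0.95)
  expect_gte(f0, 0.95)
  phc <- bare_phantom(seed = 9, transition_sigma = 0, bias_amplitude = 0.6,
                      noise_sigma = 20)
  roic <- detect_humeral_circle(phc$image)
  expect_lt(dice(gmm_segment(phc$image, roic, seed = 1)$mask, phc$truth), g0)
  expect_lt(dice(fcm_segment(phc$image, roic, seed = 1)$mask, phc$truth), f0)
})
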