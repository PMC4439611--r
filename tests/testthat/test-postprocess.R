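test_that("side detection follows the intensity mass and mirrors correctly", {
  phl <- make_phantom(phantom_spec(side = "left", seed = 2))
  phr <- make_phantom(phantom_spec(side = "right", seed = 2))
  sl <- detect_side(phl$image)
  sr <- detect_side(phr$image)
  expect_identical(sl$side, "left")
  expect_identical(sr$side, "right")
  # mirrored image flips the detected side
  mirrored <- image2d(phl$image$pixels[, rev(seq_len(phl$image$width))])
  expect_identical(detect_side(mirrored)$side, "right")
  # scapula sector points toward the detected side's border
  expect_equal(sl$sector_center, pi)
  expect_equal(sr$sector_center, 0)
  expect_warning(detect_side(image2d(matrix(5, 64, 64))), "tie")
})

test_that("a scapula arc attached through a narrow bridge is removed", {
  # head disk plus a scapula arc joined by a 3-px capsule bridge
  ph <- make_phantom(phantom_spec(
    scapula = list(arc_radius = 60, gap = 4, thickness = 6, span = 90,
                   intensity = 190, bridge_width = 3),
    tendon = NULL, transition_sigma = 0, seed = 3))
  roi <- circle_roi(ph$spec$head_center, ph$spec$head_radius,
                    dim(ph$image$pixels))
  d <- boneseg:::dist_from(256, 256, ph$spec$head_center)
  raw <- binary_mask(as.matrix(ph$image) > 110 & d <= roi$enlarged_radius)
  side <- detect_side(ph$image)
  cleaned <- suppress_attachments(raw, roi, side)
  expect_gte(dice(cleaned, ph$truth), 0.97)
  expect_lt(sum(cleaned$pixels), sum(raw$pixels))
})

test_that("a lone head disk passes through the opening nearly unchanged", {
  ph <- bare_phantom(seed = 5, transition_sigma = 0)
  roi <- circle_roi(ph$spec$head_center, ph$spec$head_radius,
                    dim(ph$image$pixels))
  side <- detect_side(ph$image)
  out <- suppress_attachments(ph$truth, roi, side)
  expect_gte(dice(out, ph$truth), 0.99)
  expect_lte(sum(out$pixels), sum(ph$truth$pixels))  # opening never adds
})

test_that("empty masks fall through with a warning", {
  roi <- circle_roi(c(64, 64), 20, c(128, 128))
  side <- structure(list(side = "right", sector_center = 0,
                         sector_halfwidth = pi / 4), class = "side_info")
  expect_warning(out <- suppress_attachments(binary_mask(matrix(0, 128, 128)),
                                             roi, side), "empty")
  expect_identical(sum(out$pixels), 0L)
})

test_that("hole filling turns an annulus into a disk, is idempotent and monotone", {
  d <- boneseg:::dist_from(64, 64, c(32, 32))
  annulus <- binary_mask(d <= 20 & d >= 12)
  disk <- binary_mask(d <= 20)
  filled <- fill_holes(annulus)
  expect_identical(filled$pixels, disk$pixels)
  expect_identical(fill_holes(disk)$pixels, disk$pixels)   # idempotent
  expect_true(all(filled$pixels >= annulus$pixels))        # monotone
})

test_that("boundary extraction traces the outer border in order", {
  m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
  b <- extract_boundary(binary_mask(m))
  expect_equal(nrow(b), 8)  # 3x3 square: 8 perimeter pixels
  expect_setdiff <- setdiff(paste(b[, 1], b[, 2]),
                            c("3 3","3 4","3 5","4 3","4 5","5 3","5 4","5 5"))
  expect_length(expect_setdiff, 0)
  # consecutive boundary pixels are 8-connected neighbors
  steps <- abs(diff(b))
  expect_true(all(steps <= 1))
})

test_that("boundary length of a disk approximates its circumference", {
  for (r in c(12, 25)) {
    d <- boneseg:::dist_from(64, 64, c(32, 32))
    b <- extract_boundary(binary_mask(d <= r))
    # polygon length with diagonal steps weighted sqrt(2), closed
    steps <- rbind(abs(diff(b)), abs(b[1, ] - b[nrow(b), ]))
    len <- sum(ifelse(rowSums(steps) == 2, sqrt(2), 1))
    expect_lt(abs(len - 2 * pi * r) / (2 * pi * r), 0.15)
  }
})

test_that("only the largest component is traced; empty mask errors", {
  m <- matrix(0, 32, 32); m[4:12, 4:12] <- 1; m[25:27, 25:27] <- 1
  b <- extract_boundary(binary_mask(m))
  expect_true(all(b[, 1] <= 12 & b[, 2] <= 12))
  expect_error(extract_boundary(binary_mask(matrix(0, 8, 8))), "empty")
})

test_that("full postprocessing fills edema holes and improves Dice", {
  d <- boneseg:::dist_from(256, 256, c(128, 110))
  truth <- binary_mask(d <= 40)
  holed <- binary_mask(d <= 40 & boneseg:::dist_from(256, 256, c(120, 105)) > 8)
  roi <- circle_roi(c(128, 110), 40, c(256, 256))
  side <- structure(list(side = "left", sector_center = pi,
                         sector_halfwidth = pi / 4), class = "side_info")
  res <- segmentation_result(holed, extract_boundary(holed), "acwe", 1L)
  post <- postprocess_result(res, roi, side)
  expect_gt(dice(post$mask, truth), dice(holed, truth))
  expect_gte(dice(post$mask, truth), 0.99)
})
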