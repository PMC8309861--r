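# Class activation maps, pixelwise softmax, component filtering, and the
# full segmentation path with a plug-in colour-oracle classifier.

test_that("CAM is the exact weighted sum of feature maps", {
  maps <- array(c(2, 3), c(1, 1, 2))
  expect_equal(as.numeric(compute_cams(maps, matrix(c(0.5, -1), 1))), -2)
  withr::with_seed(6, {
    maps <- array(rnorm(7 * 5 * 32), c(7, 5, 32))
    head_w <- matrix(rnorm(3 * 32), 3, 32)
    expect_equal(compute_cams(maps, head_w), cam_oracle(maps, head_w),
                 tolerance = 1e-10)
    expect_equal(compute_cams(maps, matrix(0, 3, 32)),
                 array(0, c(7, 5, 3)))
    expect_error(compute_cams(maps, matrix(0, 3, 16)), "feature maps")
  })
})

test_that("mean CAM activation equals the class logit (GAP equivalence)", {
  withr::with_seed(8, {
    maps <- array(abs(rnorm(6 * 6 * 24)), c(6, 6, 24))
    head_w <- matrix(rnorm(3 * 24), 3, 24)
    cams <- compute_cams(maps, head_w)
    logits <- as.numeric(head_w %*% global_average_pool(maps))
    expect_equal(apply(cams, 3, mean), logits, tolerance = 1e-10)
  })
})

test_that("pixelwise softmax has the closed form and conserves sums", {
  cams <- array(0, c(4, 4, 2))
  p <- pixel_class_probabilities(cams)
  expect_equal(p, array(0.5, c(4, 4, 2)))
  cams3 <- array(0, c(1, 1, 3)); cams3[1, 1, 1] <- 1
  p3 <- pixel_class_probabilities(cams3)
  expect_equal(p3[1, 1, 1], exp(1) / (exp(1) + 2), tolerance = 1e-12)
  withr::with_seed(9, {
    cams <- array(rnorm(5 * 4 * 3, sd = 10), c(5, 4, 3))
    pn <- pixel_class_probabilities(cams)
    expect_lt(max(abs(apply(pn, c(1, 2), sum) - 1)), 1e-6)
    up <- pixel_class_probabilities(cams, out_size = c(40, 32))
    expect_equal(dim(up), c(40, 32, 3))
    expect_lt(max(abs(apply(up, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(up >= 0 & up <= 1))
  })
  expect_error(pixel_class_probabilities(array(0, c(2, 2, 1))), "2 classes")
})

test_that("component filtering matches the flood-fill oracle", {
  m <- matrix(0L, 30, 30)
  m[5:14, 5:14] <- 1L          # 100 px blob
  m[25, c(3, 4)] <- 1L         # 2 px speck
  f <- filter_small_components(m, min_area = 10)
  lab <- label8_oracle(m)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= 10)
  expect_identical(f$mask, matrix(as.integer(lab %in% keep), 30))
  expect_equal(sum(f$mask), 100L)
  expect_equal(nrow(f$components), 1L)
  expect_equal(f$components$area, 100L)
})

test_that("diagonal pixels connect (8-connectivity)", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:4, 1:4)] <- 1L
  f <- filter_small_components(m, min_area = 4)
  expect_equal(sum(f$mask), 4L)  # one 4-px diagonal component survives
  expect_identical(cropcam:::cc_label8(m) > 0, label8_oracle(m) > 0)
  expect_equal(max(cropcam:::cc_label8(m)), max(label8_oracle(m)))
})

test_that("filtering is idempotent, monotone in min_area, and no-op at 0", {
  withr::with_seed(10, {
    m <- matrix(as.integer(runif(40 * 40) < 0.3), 40, 40)
    expect_identical(filter_small_components(m, 0)$mask, m)
    prev <- Inf
    for (a in c(0, 2, 5, 10, 50)) {
      f <- filter_small_components(m, a)
      expect_identical(filter_small_components(f$mask, a)$mask, f$mask)
      expect_lte(sum(f$mask), prev)
      prev <- sum(f$mask)
    }
  })
})

test_that("an all-ones mask passes through the filter untouched", {
  m <- matrix(1L, 12, 12)
  f <- filter_small_components(m, 20)
  expect_identical(f$mask, m)
  expect_equal(nrow(f$components), 1L)
})

test_that("colour-oracle weights segment a noiseless scene at IoU >= 0.98", {
  om <- make_color_oracle_model(input_size = 360)
  sp <- scene_spec(width = 360, height = 360, horizon_row = 136,
                   edge_bottom_x = 200, edge_angle_deg = 0, noise_sigma = 0)
  s <- generate_scene(sp)
  seg <- segment_crop_area(s$image, om)
  expect_gte(intersection_over_union(seg, s$gt_polygon), 0.98)
})

test_that("a scene with no crop yields an empty mask after filtering", {
  om <- make_color_oracle_model(input_size = 176)
  sp <- small_spec(edge_bottom_x = 0, width = 180L, height = 180L,
                   horizon_row = 68L)
  s <- generate_scene(sp)
  expect_equal(sum(s$mask == 1L), 0L)
  seg <- segment_crop_area(s$image, om, infer_size = 176)
  expect_equal(sum(seg$mask), 0L)
})

test_that("segmentation refuses untrained models and bad sizes", {
  m <- build_model(backbone_config(input_size = 16))
  img <- array(0, c(16, 16, 3))
  expect_error(segment_crop_area(img, m), "untrained")
  om <- make_color_oracle_model(input_size = 176)
  expect_error(segment_crop_area(img, om, infer_size = 20), "divisible by 8")
})

test_that("masks are registered back to the original frame size", {
  om <- make_color_oracle_model(input_size = 176)
  sp <- small_spec(edge_bottom_x = 100, width = 200L, height = 200L,
                   horizon_row = 76L, noise_sigma = 0)
  s <- generate_scene(sp)
  seg <- segment_crop_area(s$image, om, infer_size = 176)
  expect_equal(dim(seg$mask), c(200L, 200L))
  expect_gte(intersection_over_union(seg, s$gt_polygon), 0.85)
})
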