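# Contour extraction, trimming/rightmost filtering, Hough line fitting,
# and the composed uncut-edge detector.

test_that("boundary extraction matches the morphological oracle", {
  withr::with_seed(11, {
    m <- matrix(0L, 25, 25)
    m[4:18, 6:20] <- 1L
    m[15:24, 2:7] <- 1L   # overlapping second rectangle -> L-shape
    b <- extract_boundary_pixels(m)
    o <- boundary_oracle(m)
    expect_equal(b[order(b[, 1], b[, 2]), , drop = FALSE],
                 o[order(o[, 1], o[, 2]), , drop = FALSE],
                 ignore_attr = TRUE)
  })
})

test_that("rectangle boundary has the perimeter pixel count", {
  m <- matrix(0L, 40, 40)
  m[10:29, 5:24] <- 1L  # 20 x 20
  b <- extract_boundary_pixels(m)
  expect_lte(abs(nrow(b) - (2 * 20 + 2 * 20 - 4)), 4)
})

test_that("a full-frame mask's boundary is the image border", {
  m <- matrix(1L, 15, 18)
  b <- extract_boundary_pixels(m)
  expect_equal(nrow(b), 2 * 15 + 2 * 18 - 4)
  expect_true(all(b[, 1] %in% c(0, 17) | b[, 2] %in% c(0, 14)))
})

test_that("empty masks raise emptyMaskError", {
  expect_error(extract_boundary_pixels(matrix(0L, 5, 5)),
               class = "emptyMaskError")
})

test_that("vertical trim keeps rightmost pixels of the central 80% rows", {
  # rectangle boundary spanning rows 0..99, right side at x = 200
  xs <- c(rep(100, 100), rep(200, 100), 101:199, 101:199)
  ys <- c(0:99, 0:99, rep(0, 99), rep(99, 99))
  b <- cbind(x = xs, y = ys)
  f <- trim_and_filter_rightmost(b, 0.10)
  expect_equal(nrow(f), 80L)
  expect_true(all(f[, 1] == 200))
  expect_equal(sort(f[, 2]), 10:89)
})

test_that("zero trim keeps one rightmost pixel per occupied row", {
  b <- cbind(x = c(3, 9, 4, 1), y = c(0, 0, 5, 9))
  f <- trim_and_filter_rightmost(b, 0)
  expect_equal(nrow(f), 3L)
  expect_equal(unname(f[f[, 2] == 0, 1]), 9)
})

test_that("contours narrower than 3 rows are degenerate", {
  b <- cbind(x = 0:9, y = rep(2, 10))
  expect_error(trim_and_filter_rightmost(b), class = "degenerateContourError")
  b2 <- cbind(x = 0:9, y = rep(c(2, 3), 5))
  expect_error(trim_and_filter_rightmost(b2),
               class = "degenerateContourError")
  expect_true(is.matrix(
    trim_and_filter_rightmost(cbind(x = 1:3, y = 0:2), 0.1)))
})

test_that("the trim never enlarges the pixel set", {
  withr::with_seed(12, {
    b <- cbind(x = sample(0:50, 80, TRUE), y = sample(0:30, 80, TRUE))
    f <- trim_and_filter_rightmost(b, 0.1)
    key <- function(m) paste(m[, 1], m[, 2])
    expect_true(all(key(f) %in% key(b)))
  })
})

test_that("perfect vertical consensus recovers the line within quantization", {
  px <- cbind(x = rep(120, 50), y = 0:49)
  line <- fit_edge_line(px, height = 50)
  expect_lt(abs(line$bottom_x - 120), 1)
  expect_lt(abs(vertical_angle(line)), 1)
  expect_gte(attr(line, "n_lines_averaged"), 1)
  expect_equal(attr(line, "n_filtered_pixels"), 50)
})

test_that("a 45-degree line is recovered within a degree", {
  px <- cbind(x = 0:49, y = 0:49)
  line <- fit_edge_line(px, height = 50)
  expect_lt(abs(vertical_angle(line) - (-45)), 1)
})

test_that("scattered pixels below the vote threshold raise noLineError", {
  withr::with_seed(13, {
    px <- cbind(x = sample(0:90, 10), y = sample(0:90, 10))
    expect_error(fit_edge_line(px, height = 91, vote_threshold = 15),
                 class = "noLineError")
    expect_error(fit_edge_line(px[1:3, ], height = 91), class = "noLineError")
  })
})

test_that("ground-truth masks yield the generator's line within 2 px / 1 deg", {
  for (case in list(c(40, -10), c(70, 0), c(95, 12), c(60, -18))) {
    sp <- small_spec(edge_bottom_x = case[1], edge_angle_deg = case[2],
                     width = 180L, height = 180L, horizon_row = 68L)
    s <- generate_scene(sp)
    line <- detect_uncut_edge(matrix(as.integer(s$mask == 1L), 180))
    expect_lt(abs(line$bottom_x - s$gt_edge$bottom_x), 2)
    expect_lt(abs(vertical_angle(line) - case[2]), 1)
  }
})

test_that("an edge clipped by the frame collapses to the image border", {
  sp <- small_spec(edge_bottom_x = 119, edge_angle_deg = 0, width = 120L)
  s <- generate_scene(sp)
  line <- detect_uncut_edge(matrix(as.integer(s$mask == 1L), 120))
  expect_lt(abs(line$bottom_x - 119), 2)
})

test_that("translating the mask translates bottom_x equally", {
  sp <- small_spec(edge_bottom_x = 60, edge_angle_deg = 8, width = 180L,
                   height = 180L, horizon_row = 68L)
  s <- generate_scene(sp)
  m <- matrix(as.integer(s$mask == 1L), 180)
  l0 <- detect_uncut_edge(m)
  for (d in c(5, 12)) {
    m2 <- cbind(matrix(0L, 180, d), m[, 1:(180 - d)])
    l2 <- detect_uncut_edge(m2)
    expect_lt(abs((l2$bottom_x - l0$bottom_x) - d), 1.5)
  }
})

test_that("rotating the boundary rotates the recovered angle consistently", {
  base <- 0
  for (alpha in c(-10, 5, 15)) {
    sp <- small_spec(edge_bottom_x = 70, edge_angle_deg = base + alpha,
                     width = 180L, height = 180L, horizon_row = 68L)
    s <- generate_scene(sp)
    line <- detect_uncut_edge(matrix(as.integer(s$mask == 1L), 180))
    expect_lt(abs(vertical_angle(line) - (base + alpha)), 1)
  }
})

test_that("multi-component masks are flagged and still fit a line", {
  sp <- small_spec(edge_bottom_x = 70, width = 180L, height = 180L,
                   horizon_row = 68L)
  s <- generate_scene(sp)
  m <- matrix(as.integer(s$mask == 1L), 180)
  m[5:20, 150:170] <- 1L   # secondary blob far from the crop area
  seg <- filter_small_components(m, 10)
  line <- detect_uncut_edge(seg)
  expect_true(attr(line, "multi_component"))
  expect_s3_class(line, "edge_line")
})

test_that("edge_line canonicalizes theta into [0, 180)", {
  l <- edge_line(rho = 50, theta_deg = -10, height = 100)
  expect_equal(l$theta_deg, 170)
  expect_equal(l$rho, -50)
  expect_equal(vertical_angle(l), -10)
  l2 <- edge_line_from_vertical(bottom_x = 80, angle_deg = -10, height = 100)
  expect_equal(l2$bottom_x, 80, tolerance = 1e-9)
})
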