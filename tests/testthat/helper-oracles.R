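# Independent oracles and small fixture builders used across the suite.
# Every oracle deliberately uses a different algorithm from the package
# code path it checks.

# Small fast scene used throughout: 120x120, horizon at 46, field band 74.
small_spec <- function(edge_bottom_x = 70, edge_angle_deg = 0,
                       noise_sigma = 0, seed = 1L, width = 120L,
                       height = 120L, horizon_row = 46L) {
  scene_spec(width = width, height = height, horizon_row = horizon_row,
             edge_bottom_x = edge_bottom_x, edge_angle_deg = edge_angle_deg,
             noise_sigma = noise_sigma, seed = seed)
}

# crossing-number point-in-polygon (PNPOLY), evaluated per pixel centre --
# an O(H*W*E) alternative to the package's scanline rasterizer.
point_in_polygon_oracle <- function(poly, height, width) {
  out <- matrix(0L, height, width)
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  for (row in seq_len(height) - 1L) {
    for (col in seq_len(width) - 1L) {
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((py[i] > row) != (py[j] > row)) {
          xint <- px[i] + (row - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
          if (col < xint) inside <- !inside
        }
        j <- i
      }
      if (inside) out[row + 1L, col + 1L] <- 1L
    }
  }
  out
}

# 8-connected labeling by iterated minimum-label propagation (fixpoint),
# independent of the package's BFS.
label8_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  repeat {
    prev <- lab
    big <- matrix(Inf, H + 2, W + 2)
    big[2:(H + 1), 2:(W + 1)][mask != 0] <- lab[mask != 0]
    nb <- big[2:(H + 1), 2:(W + 1)]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pmin(nb, big[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)])
    }
    upd <- mask != 0 & is.finite(nb) & nb < lab
    lab[upd] <- nb[upd]
    if (identical(lab, prev)) break
  }
  # renumber compactly in first-occurrence order
  ids <- unique(lab[lab > 0])
  for (k in seq_along(ids)) lab[lab == ids[k]] <- -k
  -lab
}

# morphological outer boundary by explicit per-pixel neighbour checks
boundary_oracle <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  res <- NULL
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (mask[i, j] == 0) next
      on_border <- i == 1 || i == H || j == 1 || j == W
      touches_bg <- (i > 1 && mask[i - 1, j] == 0) ||
        (i < H && mask[i + 1, j] == 0) ||
        (j > 1 && mask[i, j - 1] == 0) ||
        (j < W && mask[i, j + 1] == 0)
      if (on_border || touches_bg) res <- rbind(res, c(j - 1L, i - 1L))
    }
  }
  res
}

# exhaustive window purity count
purity_oracle <- function(mask, label, x0, y0, w, h) {
  win <- mask[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w)]
  sum(win == label) / (w * h)
}

# brute-force GAP: scalar loop over every pixel of every map
gap_oracle <- function(maps) {
  d <- dim(maps)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + maps[i, j, k]
    out[k] <- s / (d[1] * d[2])
  }
  out
}

# brute-force CAM: per-pixel weighted sum loop
cam_oracle <- function(maps, head) {
  d <- dim(maps)
  out <- array(0, c(d[1], d[2], nrow(head)))
  for (c in seq_len(nrow(head)))
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        out[i, j, c] <- sum(head[c, ] * maps[i, j, ])
  out
}

# A classifier whose weights are set by hand to implement a nearest-mean
# colour classifier: conv layers pass the (shifted) RGB channels plus a
# constant-1 channel through; the bias-free head encodes the linear form
# of nearest-class-mean, 2*mu.x - |mu|^2, with the constant channel acting
# as the bias. Classifies the generator's three textures correctly without
# any training -- a plug-in oracle for the segmentation path.
make_color_oracle_model <- function(input_size = 176) {
  m <- build_model(backbone_config(input_size = input_size))
  w <- m$weights
  w$conv[[1]]$w[] <- 0
  w$conv[[1]]$w[cbind(c(5, 14, 23), 1:3)] <- 1  # centre taps of R,G,B
  w$conv[[1]]$b[] <- 0
  w$conv[[1]]$b[1:3] <- 0.5                     # undo the [-0.5,0.5] shift
  w$conv[[1]]$b[4] <- 1                         # constant-1 channel
  for (l in 2:4) {
    w$conv[[l]]$w[] <- 0
    for (k in 1:4) w$conv[[l]]$w[(k - 1) * 9 + 5, k] <- 1
    w$conv[[l]]$b[] <- 0
  }
  tex <- default_texture_params()
  mu <- rbind((tex$background$top + tex$background$bottom) / 2,
              tex$crop$base, tex$harvested$base) / 255
  w$head[] <- 0
  w$head[, 1:3] <- 2 * mu
  w$head[, 4] <- -rowSums(mu^2)
  m$weights <- w
  m$trained <- TRUE
  m
}

# solid-colour labeled patches for separable-training sanity checks
make_solid_split <- function(n_per_class = 4, side = 24, jitter = 5,
                             seed = 3) {
  cols <- list(c(200, 60, 60), c(60, 200, 60), c(60, 60, 200))
  tr <- list(); va <- list()
  withr::with_seed(seed, {
    for (cl in 0:2) {
      for (i in seq_len(2 * n_per_class)) {
        px <- array(rep(cols[[cl + 1]], each = side * side),
                    c(side, side, 3)) +
          array(rnorm(side * side * 3, 0, jitter), c(side, side, 3))
        p <- structure(list(pixels = pmin(pmax(px, 0), 255), label = cl,
                            source_frame = cl * 100L + i,
                            purity = 1, x0 = 0, y0 = 0, w = side, h = side),
                       class = "labeled_patch")
        if (i <= n_per_class) tr <- c(tr, list(p)) else va <- c(va, list(p))
      }
    }
  })
  structure(list(train = tr, val = va, skipped = data.frame(),
                 crop_size = side), class = "patch_split")
}
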