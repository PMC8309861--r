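# Synthetic combine-harvester front-view scenes. Each scene has three
# regions separable by local colour/texture -- the only cue a patch-trained
# classifier ever sees:
#   0 background : sky / far field, vertical luminance gradient + noise
#   1 uncut crop : dense near-vertical strokes in a green-yellow family
#   2 harvested  : horizontal stubble stripes + speckle in a brown family
# The crop/harvested boundary is a near-vertical line whose bottom
# intersection and lean angle are the ground truth for edge detection.

#' Specification of one synthetic scene
#'
#' @param width,height canvas size in pixels.
#' @param horizon_row row index where the background band ends and the field
#'   begins; 0 <= horizon_row < height.
#' @param edge_bottom_x column where the crop/harvested boundary meets the
#'   bottom row; 0 <= edge_bottom_x < width.
#' @param edge_angle_deg signed lean of the boundary from the image vertical
#'   axis, degrees (positive = top leans right); |angle| <= 30.
#' @param texture_params per-class colour means, jitter amplitudes and
#'   stroke/stripe densities; see [default_texture_params()].
#' @param noise_sigma additive Gaussian pixel noise s.d. on the 0-255 scale.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 360, height = 360,
                       horizon_row = round(0.38 * height),
                       edge_bottom_x = round(width / 2),
                       edge_angle_deg = 0,
                       texture_params = default_texture_params(),
                       noise_sigma = 6, seed = 1L) {
  spec <- structure(list(width = as.integer(width), height = as.integer(height),
                         horizon_row = as.integer(horizon_row),
                         edge_bottom_x = edge_bottom_x,
                         edge_angle_deg = edge_angle_deg,
                         texture_params = texture_params,
                         noise_sigma = noise_sigma, seed = as.integer(seed)),
                    class = "scene_spec")
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  with(spec, {
    if (width < 8 || height < 8) stop("scene too small")
    if (horizon_row < 0 || horizon_row >= height)
      stop("horizon_row must lie in [0, height)")
    if (edge_bottom_x < 0 || edge_bottom_x >= width)
      stop_with("invalidGeometryError",
                "edge_bottom_x = %.1f puts the boundary outside the field band [0, %d)",
                edge_bottom_x, width)
    if (abs(edge_angle_deg) > 30)
      stop("|edge_angle_deg| must be <= 30 (near-vertical boundary)")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  })
  invisible(TRUE)
}

#' Default per-class texture parameters
#'
#' Colour means are RGB on the 0-255 scale; jitters are Gaussian s.d. values.
#' @return named list with `crop`, `harvested`, `background` entries.
#' @export
default_texture_params <- function() {
  list(
    crop = list(base = c(105, 150, 60), stroke_sd = 30, row_sd = 10,
                dark_frac = 0.12, dark_delta = -35,
                hue_dir = c(0.35, 1, 0.25)),
    harvested = list(base = c(160, 120, 75), stripe_sd = 22, stripe_h = 3,
                     speckle_frac = 0.06, speckle_delta = -45, pixel_sd = 8,
                     hue_dir = c(1, 0.8, 0.55)),
    background = list(top = c(170, 190, 210), bottom = c(215, 218, 222),
                      sd = 4)
  )
}

# Continuous x of the crop/harvested boundary at row y (pixel coordinates)
boundary_x_at <- function(spec, y) {
  spec$edge_bottom_x + (spec$height - 1 - y) * tan(spec$edge_angle_deg * pi / 180)
}

# Crop-region polygon in continuous pixel coordinates. The region is the
# part of the field band left of the boundary line; rasterization at pixel
# centers (fill rule: centre x with ceil(a) <= x < ceil(b)) then labels a
# pixel crop exactly when its centre lies strictly left of the boundary,
# so every crop pixel is within 1 px of the ground-truth line. Clipped to
# the canvas with Sutherland-Hodgman.
crop_polygon <- function(spec) {
  h <- spec$height; w <- spec$width
  ytop <- spec$horizon_row - 0.5; ybot <- h - 0.5
  gt <- boundary_x_at(spec, ytop)
  gb <- boundary_x_at(spec, ybot)
  poly <- rbind(c(-0.5, ytop), c(gt, ytop), c(gb, ybot), c(-0.5, ybot))
  poly <- clip_halfplane(poly, 1, w - 0.5, keep_less = TRUE)
  poly <- clip_halfplane(poly, 1, -0.5, keep_less = FALSE)
  poly
}

# Sutherland-Hodgman clip against coordinate `axis` (1 = x, 2 = y)
clip_halfplane <- function(poly, axis, bound, keep_less) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  inside <- function(p) if (keep_less) p[axis] <= bound else p[axis] >= bound
  out <- NULL
  n <- nrow(poly)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    ain <- inside(a); bin <- inside(b)
    if (ain) out <- rbind(out, a)
    if (xor(ain, bin)) {
      t <- (bound - a[axis]) / (b[axis] - a[axis])
      out <- rbind(out, a + t * (b - a))
    }
  }
  # drop consecutive duplicates
  if (!is.null(out) && nrow(out) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(out))) > 1e-12)
    out <- out[keep, , drop = FALSE]
    if (nrow(out) > 1 && sum(abs(out[1, ] - out[nrow(out), ])) < 1e-12)
      out <- out[-nrow(out), , drop = FALSE]
  }
  out
}

render_layer_crop <- function(h, w, p) {
  # vertical strokes 1-2 px wide with per-stroke hue jitter
  widths <- sample(1:2, w, replace = TRUE)
  stroke_id <- rep(seq_along(widths), widths)[seq_len(w)]
  jit <- rnorm(max(stroke_id), 0, p$stroke_sd)[stroke_id]     # per column
  dark <- (runif(max(stroke_id)) < p$dark_frac)[stroke_id] * p$dark_delta
  lum <- matrix(rnorm(h * w, 0, p$row_sd), h, w)              # breaks strokes up
  layer <- array(0, c(h, w, 3))
  for (ch in 1:3)
    layer[, , ch] <- p$base[ch] +
      matrix(jit * p$hue_dir[ch] + dark, h, w, byrow = TRUE) + lum
  layer
}

render_layer_harvested <- function(h, w, p) {
  stripe_id <- (seq_len(h) - 1L) %/% p$stripe_h + 1L
  jit <- rnorm(max(stripe_id), 0, p$stripe_sd)[stripe_id]     # per row
  speck <- matrix((runif(h * w) < p$speckle_frac) * p$speckle_delta, h, w)
  px <- matrix(rnorm(h * w, 0, p$pixel_sd), h, w)
  layer <- array(0, c(h, w, 3))
  for (ch in 1:3)
    layer[, , ch] <- p$base[ch] + jit * p$hue_dir[ch] + speck + px
  layer
}

render_layer_background <- function(h, w, p) {
  t <- (seq_len(h) - 1) / max(1, h - 1)
  layer <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    grad <- p$top[ch] + t * (p$bottom[ch] - p$top[ch])
    layer[, , ch] <- grad + matrix(rnorm(h * w, 0, p$sd), h, w)
  }
  layer
}

#' Generate one synthetic scene
#'
#' Renders the three textured regions, composes them according to the
#' ground-truth geometry, adds pixel noise, and returns the image together
#' with its pixel-perfect class mask, edge line and crop polygon. The crop
#' mask is produced by [rasterize_polygon()] on the returned polygon, so the
#' polygon rasterizes exactly to `mask == 1` by construction.
#'
#' @param spec a [scene_spec()].
#' @return object of class `scene_sample`: list with `image` (H x W x 3
#'   integer array, 0-255), `mask` (H x W integer matrix, values 0/1/2),
#'   `gt_edge` ([edge_line()]), `gt_polygon` (vertex matrix), `spec`, and
#'   `frame_id` (NA unless set by [generate_sequence()]).
#' @export
generate_scene <- function(spec) {
  validate_scene_spec(spec)
  h <- spec$height; w <- spec$width
  poly <- crop_polygon(spec)
  crop <- if (is.null(poly) || nrow(poly) < 3) matrix(0L, h, w)
          else rasterize_polygon(poly, h, w)
  mask <- matrix(0L, h, w)
  field <- seq(spec$horizon_row + 1L, h)
  mask[field, ] <- 2L
  mask[crop == 1L] <- 1L

  img <- with_seed(spec$seed, {
    tp <- spec$texture_params
    lc <- render_layer_crop(h, w, tp$crop)
    lh <- render_layer_harvested(h, w, tp$harvested)
    lb <- render_layer_background(h, w, tp$background)
    noise <- array(rnorm(h * w * 3, 0, spec$noise_sigma), c(h, w, 3))
    out <- lb
    mh <- mask == 2L; mc <- mask == 1L
    for (ch in 1:3) {
      o <- out[, , ch]
      o[mh] <- lh[, , ch][mh]
      o[mc] <- lc[, , ch][mc]
      out[, , ch] <- o
    }
    out <- out + noise
    storage.mode(out) <- "double"
    array(as.integer(round(clamp(out, 0, 255))), c(h, w, 3))
  })

  structure(list(image = img, mask = mask,
                 gt_edge = edge_line_from_vertical(spec$edge_bottom_x,
                                                   spec$edge_angle_deg, h),
                 gt_polygon = poly, spec = spec, frame_id = NA_integer_),
            class = "scene_sample")
}

#' @export
print.scene_sample <- function(x, ...) {
  cat(sprintf("scene %s: %d x %d, classes bg/crop/harv = %d/%d/%d px, edge bottom_x = %.1f, angle = %.1f deg\n",
              ifelse(is.na(x$frame_id), "-", x$frame_id),
              x$spec$width, x$spec$height,
              sum(x$mask == 0L), sum(x$mask == 1L), sum(x$mask == 2L),
              x$spec$edge_bottom_x, x$spec$edge_angle_deg))
  invisible(x)
}

#' Generate a harvest sequence with a drifting crop edge
#'
#' Frame i (0-based) applies `i` times the per-frame drift to the boundary
#' position and angle and uses seed `spec$seed + i`, emulating the shrinking
#' uncut area as the harvester works. Frames whose drifted geometry leaves
#' the canvas truncate the sequence with a warning.
#'
#' @param n_frames number of frames (>= 1).
#' @param start_spec [scene_spec()] for frame 0.
#' @param drift named list/vector: `edge_bottom_x` (px/frame) and
#'   `edge_angle_deg` (deg/frame) deltas; defaults 0.
#' @return list of `scene_sample` (class `scene_sequence`); attribute
#'   `truncated_at` gives the index of the first invalid frame when
#'   truncation occurred.
#' @export
generate_sequence <- function(n_frames, start_spec,
                              drift = list(edge_bottom_x = 0, edge_angle_deg = 0)) {
  stopifnot(n_frames >= 1)
  dx <- drift$edge_bottom_x %||% 0
  da <- drift$edge_angle_deg %||% 0
  out <- vector("list", n_frames)
  for (i in seq_len(n_frames) - 1L) {
    sp <- start_spec
    sp$edge_bottom_x <- start_spec$edge_bottom_x + i * dx
    sp$edge_angle_deg <- start_spec$edge_angle_deg + i * da
    sp$seed <- start_spec$seed + i
    ok <- tryCatch({ validate_scene_spec(sp); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      out <- out[seq_len(i)]
      warning(sprintf("drift leaves the canvas at frame %d; sequence truncated to %d frames",
                      i, i))
      attr(out, "truncated_at") <- i
      class(out) <- "scene_sequence"
      return(out)
    }
    s <- generate_scene(sp)
    s$frame_id <- i
    out[[i + 1L]] <- s
  }
  class(out) <- "scene_sequence"
  out
}

#' Frame indices of a subsampled video stream
#'
#' A recording captured at video rate is thinned to analysis frames by
#' keeping every `every`-th frame, e.g. a 5-minute 30-fps stream (9000
#' frames) thinned every 15th gives 600 frames at 2 Hz.
#'
#' @param n_total total frames in the stream.
#' @param every keep one frame in `every`.
#' @return integer vector of kept 1-based frame indices.
#' @export
subsample_stream <- function(n_total, every = 15L) {
  stopifnot(n_total >= 1, every >= 1)
  seq(1L, as.integer(n_total), by = as.integer(every))
}
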