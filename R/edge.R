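# Uncut-crop-edge extraction: the segmented crop area's outer contour is
# reduced to the pixels that can belong to the right-hand (uncut) edge --
# trim 10% of the contour's own row extent top and bottom, keep the
# rightmost pixel per remaining row -- and a rho-theta Hough accumulator
# over those pixels votes for near-vertical lines whose parameters are
# averaged into one guidance line.

as_mask_matrix <- function(mask) {
  if (inherits(mask, "crop_segmentation")) mask <- mask$mask
  matrix(as.integer(mask != 0), nrow(mask))
}

#' Boundary pixels of a segmentation mask
#'
#' The outer morphological boundary: mask pixels with a 4-neighbour outside
#' the mask, or lying on the image border. On a binary mask this coincides
#' (to within 1 px) with the contour a Canny detector traces on the 0/255
#' rendering of the mask.
#'
#' @param mask binary matrix or `crop_segmentation`.
#' @return n x 2 matrix of 0-based pixel coordinates, columns `x`
#'   (column) and `y` (row).
#' @export
extract_boundary_pixels <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m == 1L)) stop_with("emptyMaskError", "mask has no foreground")
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  b <- which(core == 1L & nb_min == 0L, arr.ind = TRUE)
  cbind(x = b[, 2] - 1L, y = b[, 1] - 1L)
}

#' Trim the contour vertically and keep rightmost pixels
#'
#' Rows in the top and bottom `trim_fraction` of the contour's own row
#' extent are discarded; each remaining occupied row contributes its
#' maximum-x pixel. This isolates the right-hand side of the contour, the
#' side in contact with the harvested area.
#'
#' @param boundary n x 2 (x, y) pixel matrix from
#'   [extract_boundary_pixels()].
#' @param trim_fraction fraction of the row extent trimmed at each end.
#' @return m x 2 (x, y) pixel matrix, one row per retained image row.
#' @export
trim_and_filter_rightmost <- function(boundary, trim_fraction = 0.10) {
  if (is.null(nrow(boundary)) || nrow(boundary) == 0)
    stop_with("emptyMaskError", "empty boundary")
  ys <- boundary[, 2]
  extent <- max(ys) - min(ys) + 1L
  if (extent < 3L)
    stop_with("degenerateContourError",
              "contour row extent %d is too small to trim", extent)
  k <- floor(trim_fraction * extent)
  lo <- min(ys) + k; hi <- max(ys) - k
  keep <- boundary[ys >= lo & ys <= hi, , drop = FALSE]
  if (nrow(keep) == 0)
    stop_with("degenerateContourError", "all contour rows trimmed")
  xr <- tapply(keep[, 1], keep[, 2], max)
  cbind(x = as.numeric(xr), y = as.numeric(names(xr)))
}

#' Fit a single line to edge pixels by Hough voting
#'
#' Standard rho-theta accumulator restricted to near-vertical normals
#' (theta within `theta_range` degrees of 0, i.e. lines within 45 degrees
#' of vertical by default), quantized at `rho_res` pixels and `theta_res`
#' degrees. Every accumulator cell reaching `vote_threshold` votes is a
#' candidate line; the result averages their rho and takes the circular
#' mean (period 180 degrees) of their theta, each candidate weighted by
#' its vote count so weakly supported quantization neighbours cannot drag
#' the consensus.
#'
#' @param pixels n x 2 (x, y) matrix.
#' @param height image height, needed to place the bottom intersection.
#' @param rho_res,theta_res accumulator bin sizes (px, degrees).
#' @param theta_range half-width of the explored normal-angle window,
#'   degrees.
#' @param vote_threshold minimum votes for a cell to count as a line;
#'   default 30% of the pixel count.
#' @param min_votes minimum number of input pixels required.
#' @return an [edge_line()] with attributes `n_lines_averaged` and
#'   `n_filtered_pixels`.
#' @export
fit_edge_line <- function(pixels, height, rho_res = 1, theta_res = 1,
                          theta_range = 45, vote_threshold = NULL,
                          min_votes = 5) {
  n <- nrow(pixels)
  if (is.null(n) || n < min_votes)
    stop_with("noLineError", "only %d pixels; need at least %d",
              n %||% 0, min_votes)
  thr <- vote_threshold %||% (0.3 * n)
  thetas <- seq(-theta_range, theta_range, by = theta_res)
  x <- pixels[, 1]; y <- pixels[, 2]
  cand_rho <- c(); cand_theta <- c(); cand_votes <- c()
  for (th in thetas) {
    a <- th * pi / 180
    rho <- x * cos(a) + y * sin(a)
    bin <- floor(rho / rho_res + 0.5)
    tb <- table(bin)
    hit <- tb[tb >= thr]
    if (length(hit)) {
      cand_rho <- c(cand_rho, as.numeric(names(hit)) * rho_res)
      cand_theta <- c(cand_theta, rep(th, length(hit)))
      cand_votes <- c(cand_votes, as.numeric(hit))
    }
  }
  if (length(cand_rho) == 0)
    stop_with("noLineError",
              "no accumulator cell reached %.1f votes (n = %d)", thr, n)
  # vote-weighted circular mean of theta with period 180 degrees
  wts <- cand_votes / sum(cand_votes)
  ang2 <- cand_theta * 2 * pi / 180
  mtheta <- atan2(sum(wts * sin(ang2)), sum(wts * cos(ang2))) * 90 / pi
  line <- edge_line(sum(wts * cand_rho), mtheta, height)
  attr(line, "n_lines_averaged") <- length(cand_rho)
  attr(line, "n_filtered_pixels") <- n
  line
}

#' Detect the uncut crop edge of a segmentation mask
#'
#' Composition of [extract_boundary_pixels()], [trim_and_filter_rightmost()]
#' and [fit_edge_line()], reported in the mask's own (frame) coordinates.
#' When the mask holds several retained components, all their boundaries
#' vote and the result carries `multi_component = TRUE`.
#'
#' @param mask binary matrix or `crop_segmentation`.
#' @param trim_fraction vertical trim fraction.
#' @param ... further arguments to [fit_edge_line()].
#' @return an [edge_line()]; attribute `multi_component` flags multi-blob
#'   masks.
#' @export
detect_uncut_edge <- function(mask, trim_fraction = 0.10, ...) {
  m <- as_mask_matrix(mask)
  b <- extract_boundary_pixels(m)
  f <- trim_and_filter_rightmost(b, trim_fraction)
  line <- fit_edge_line(f, height = nrow(m), ...)
  n_comp <- if (inherits(mask, "crop_segmentation")) nrow(mask$components)
            else max(cc_label8(m))
  attr(line, "multi_component") <- n_comp > 1L
  line
}
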