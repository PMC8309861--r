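# Image-patch-classification baseline: tile the frame into fixed 80x80
# patches, classify each tile, and take the union of crop tiles as the
# mask. The backbone is fully convolutional with a GAP head, so the same
# trained classifier scores any tile size divisible by 8; the paper-style
# baseline keeps 80 px tiles, which yields the characteristic step-shaped
# block boundaries.

#' Segment a scene by patch classification
#'
#' Every complete `patch_size` tile of the image is classified; the crop
#' mask is the union of tiles labeled crop. Residual border strips narrower
#' than a tile are labeled background.
#'
#' @param image H x W x 3 array, 0-255 scale; at least one full tile.
#' @param model a trained `crop_cnn`.
#' @param patch_size tile side in pixels (divisible by 8).
#' @return `crop_segmentation` whose mask is constant on each tile;
#'   attribute `grid` holds the R x C tile label matrix.
#' @export
segment_by_patches <- function(image, model, patch_size = 80) {
  if (!inherits(model, "crop_cnn") || !isTRUE(model$trained))
    stop("model must be a trained crop_cnn")
  if (patch_size %% 8 != 0) stop("patch_size must be divisible by 8")
  d <- dim(image)
  R <- d[1] %/% patch_size; C <- d[2] %/% patch_size
  if (R < 1 || C < 1)
    stop("image ", d[1], "x", d[2], " is smaller than one ",
         patch_size, "px tile")
  grid <- matrix(NA_integer_, R, C)
  mask <- matrix(0L, d[1], d[2])
  for (r in seq_len(R)) {
    for (cc in seq_len(C)) {
      ys <- ((r - 1) * patch_size + 1):(r * patch_size)
      xs <- ((cc - 1) * patch_size + 1):(cc * patch_size)
      p <- classify(image[ys, xs, , drop = FALSE], model)
      grid[r, cc] <- unname(which.max(p)) - 1L
      if (grid[r, cc] == 1L) mask[ys, xs] <- 1L
    }
  }
  seg <- filter_small_components(mask, min_area = 0L)
  attr(seg, "grid") <- grid
  seg
}
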