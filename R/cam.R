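# From classifier to segmenter: class activation maps are the weighted sum
# of the final feature maps under the GAP head's class weights; a pixelwise
# categorical softmax over the three maps, upsampled to image resolution,
# gives per-pixel class probabilities, and the crop class's argmax region
# (cleaned by connected-component filtering) is the segmentation.

#' Class activation maps
#'
#' M_c(x, y) = sum_k w[c, k] * f_k(x, y): each class's map is the feature
#' maps weighted by that class's GAP head weights, evaluated exactly.
#'
#' @param maps h x w x K feature-map array.
#' @param head C x K head weight matrix.
#' @return h x w x C array of activation maps.
#' @export
compute_cams <- function(maps, head) {
  d <- dim(maps)
  if (ncol(head) != d[3])
    stop("head has ", ncol(head), " columns but there are ", d[3],
         " feature maps")
  m <- matrix(maps, d[1] * d[2], d[3]) %*% t(head)
  array(m, c(d[1], d[2], nrow(head)))
}

#' Per-pixel class probabilities from activation maps
#'
#' Categorical softmax across classes at every map pixel, then (optionally)
#' bilinear upsampling of each probability channel to the requested size.
#' Because linear interpolation is applied channelwise with shared weights,
#' per-pixel channel sums remain exactly 1 after upsampling.
#'
#' @param cams h x w x C activation-map array (C >= 2).
#' @param out_size NULL (native resolution) or c(H, W) target size.
#' @return H x W x C probability array; channels sum to 1 at every pixel.
#' @export
pixel_class_probabilities <- function(cams, out_size = NULL) {
  d <- dim(cams)
  if (is.null(d) || length(d) != 3L || d[3] < 2L)
    stop("cams must be an h x w x C array with at least 2 classes")
  m <- matrix(cams, d[1] * d[2], d[3])
  m <- m - apply(m, 1, max)
  e <- exp(m)
  p <- array(e / rowSums(e), d)
  if (!is.null(out_size)) p <- resize_bilinear(p, out_size[1], out_size[2])
  p
}

#' Remove small connected components from a binary mask
#'
#' 8-connected components with area below `min_area` are erased; all others
#' are untouched. Idempotent; increasing `min_area` never increases the
#' retained pixel count.
#'
#' @param mask binary (0/1) integer matrix.
#' @param min_area minimum retained component area, pixels.
#' @return object of class `crop_segmentation`: list with `mask` (filtered
#'   binary matrix) and `components` (data.frame label/area/x0/y0/x1/y1 of
#'   retained components, 0-based bounding boxes).
#' @export
filter_small_components <- function(mask, min_area) {
  mask <- matrix(as.integer(mask != 0), nrow(mask))
  lab <- cc_label8(mask)
  n <- max(lab)
  comps <- data.frame(label = integer(), area = integer(),
                      x0 = integer(), y0 = integer(),
                      x1 = integer(), y1 = integer())
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n)
    drop <- which(areas < min_area)
    if (length(drop)) mask[lab %in% drop] <- 0L
    keep <- which(areas >= min_area)
    for (k in keep) {
      w <- which(lab == k, arr.ind = TRUE)
      comps <- rbind(comps,
                     data.frame(label = k, area = areas[k],
                                x0 = min(w[, 2]) - 1L, y0 = min(w[, 1]) - 1L,
                                x1 = max(w[, 2]) - 1L, y1 = max(w[, 1]) - 1L))
    }
  }
  structure(list(mask = mask, components = comps),
            class = "crop_segmentation")
}

#' @export
print.crop_segmentation <- function(x, ...) {
  cat(sprintf("crop segmentation: %d x %d, %d crop px in %d component(s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), nrow(x$components)))
  invisible(x)
}

#' Segment the uncut crop area of a scene
#'
#' The full weak-supervision inference path: the scene is bilinearly resized
#' to the inference size, pushed through the trained backbone, the class
#' activation maps are softmaxed pixel by pixel and upsampled, every pixel
#' takes its argmax class (ties resolved toward background), the crop-class
#' mask is cleaned by connected-component filtering, and the mask is
#' registered back to the original frame size by nearest-neighbour scaling.
#'
#' @param image H x W x 3 scene array, 0-255 scale.
#' @param model a trained `crop_cnn`.
#' @param min_area component filter threshold; default 0.5% of the frame
#'   pixels.
#' @param infer_size inference side in pixels (divisible by 8); defaults to
#'   the backbone's training input size. The backbone is fully
#'   convolutional, so any multiple of 8 works.
#' @param return_probs also return the upsampled probability array.
#' @return `crop_segmentation` (mask at the original frame size) with the
#'   retained-component table; `probs` attached when requested.
#' @export
segment_crop_area <- function(image, model, min_area = NULL,
                              infer_size = NULL, return_probs = FALSE) {
  if (!inherits(model, "crop_cnn")) stop("model must be a crop_cnn")
  if (!isTRUE(model$trained))
    stop("model is untrained; fit it or load a checkpoint first")
  d <- dim(image)
  infer_size <- as.integer(infer_size %||% model$backbone$input_size)
  if (infer_size %% 8 != 0) stop("infer_size must be divisible by 8")
  x <- if (d[1] == infer_size && d[2] == infer_size) image
       else resize_bilinear(image, infer_size, infer_size)
  maps <- forward_features(x, model)
  cams <- compute_cams(maps, model$weights$head)
  probs <- pixel_class_probabilities(cams, out_size = c(infer_size, infer_size))
  # argmax with background first, so exact ties fall to background
  pm <- matrix(probs, infer_size * infer_size, 3)
  cls <- max.col(pm, ties.method = "first") - 1L
  crop <- matrix(as.integer(cls == 1L), infer_size, infer_size)
  min_area <- min_area %||% ceiling(0.005 * d[1] * d[2])
  # register to frame size first so min_area is in frame pixels
  if (d[1] != infer_size || d[2] != infer_size)
    crop <- resize_nearest(crop, d[1], d[2])
  seg <- filter_small_components(crop, min_area)
  if (return_probs) seg$probs <- probs
  seg
}
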