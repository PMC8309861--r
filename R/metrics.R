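# Evaluation against polygon ground truth: intersection-over-union by
# exact pixel counting (prediction and ground truth rasterized by the same
# rasterizer), lateral error as the bottom-row offset between estimated
# and true edge lines over image width, and angular error as the absolute
# vertical-angle difference.

#' Intersection over union of a predicted mask and a ground-truth polygon
#'
#' The polygon is rasterized at the mask's resolution with
#' [rasterize_polygon()] (the same rasterizer that draws ground-truth
#' masks) and IoU is computed by exact pixel counting. Two empty regions
#' have IoU 1 by convention.
#'
#' @param pred binary matrix or `crop_segmentation`.
#' @param gt_polygon vertex matrix of a simple polygon (or NULL/degenerate
#'   for an empty ground truth).
#' @return IoU in [0, 1].
#' @export
intersection_over_union <- function(pred, gt_polygon) {
  p <- as_mask_matrix(pred)
  g <- if (is.null(gt_polygon) || nrow(as.matrix(gt_polygon)) < 3) 0L * p
       else rasterize_polygon(gt_polygon, nrow(p), ncol(p))
  inter <- sum(p == 1L & g == 1L)
  uni <- sum(p == 1L | g == 1L)
  if (uni == 0) return(1)
  inter / uni
}

#' Lateral error between estimated and target edge lines
#'
#' Signed horizontal distance between the lines' bottom-row intersections,
#' divided by the image width; positive when the estimate lies right of the
#' target.
#'
#' @param pred,gt [edge_line()] objects.
#' @param image_width frame width in pixels.
#' @return signed unitless ratio.
#' @export
lateral_error <- function(pred, gt, image_width) {
  if (is.na(pred$bottom_x) || is.na(gt$bottom_x))
    stop("a horizontal line has no bottom-row intersection")
  (pred$bottom_x - gt$bottom_x) / image_width
}

#' Angular error between estimated and target edge lines
#'
#' Absolute difference of the lines' vertical-axis angles, wrapped into
#' [0, 90] degrees.
#'
#' @param pred,gt [edge_line()] objects.
#' @return degrees in [0, 90].
#' @export
angular_error <- function(pred, gt) {
  d <- abs(vertical_angle(pred) - vertical_angle(gt)) %% 180
  min(d, 180 - d)
}

#' Evaluate a segmentation method over a list of scenes
#'
#' Runs `segment_fun` on every frame, detects the uncut edge on the
#' resulting mask, and scores IoU / lateral / angular error against the
#' generator's ground truth. Frames where segmentation or edge detection
#' fails are recorded with the failure reason and excluded from the
#' summary (whose n is reported). Summary means of the lateral and angular
#' errors use absolute values; the per-frame table keeps signs.
#'
#' @param samples non-empty list of `scene_sample`.
#' @param segment_fun function(image) returning a mask or
#'   `crop_segmentation`.
#' @param method label recorded in the tables.
#' @param trim_fraction passed to [detect_uncut_edge()].
#' @return object of class `edge_eval`: list with `frames` (per-frame
#'   data.frame) and `summary` (one-row data.frame of mean/sd per metric).
#' @export
evaluate_run <- function(samples, segment_fun, method = "cam",
                         trim_fraction = 0.10) {
  if (length(samples) == 0) stop("empty sample list")
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    fid <- if (is.na(s$frame_id)) i - 1L else s$frame_id
    out <- data.frame(frame_id = fid, method = method, iou = NA_real_,
                      lateral_error = NA_real_,
                      angular_error_deg = NA_real_, note = "")
    res <- tryCatch({
      seg <- segment_fun(s$image)
      iou <- intersection_over_union(seg, s$gt_polygon)
      line <- detect_uncut_edge(seg, trim_fraction = trim_fraction)
      list(iou = iou,
           lat = lateral_error(line, s$gt_edge, s$spec$width),
           ang = angular_error(line, s$gt_edge))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$note <- conditionMessage(res)
    } else {
      out$iou <- res$iou
      out$lateral_error <- res$lat
      out$angular_error_deg <- res$ang
    }
    out
  })
  frames <- do.call(rbind, rows)
  ok <- !is.na(frames$iou)
  summ <- data.frame(
    method = method, n = sum(ok), n_failed = sum(!ok),
    mean_iou = mean(frames$iou[ok]), sd_iou = sd(frames$iou[ok]),
    mean_abs_lateral = mean(abs(frames$lateral_error[ok])),
    sd_abs_lateral = sd(abs(frames$lateral_error[ok])),
    mean_angular_deg = mean(frames$angular_error_deg[ok]),
    sd_angular_deg = sd(frames$angular_error_deg[ok]))
  structure(list(frames = frames, summary = summ), class = "edge_eval")
}

#' @export
print.edge_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s on %d frame(s)%s:\n", s$method, s$n,
              if (s$n_failed) sprintf(" (%d failed)", s$n_failed) else ""))
  cat(sprintf("  IoU      %.3f +/- %.3f\n", s$mean_iou, s$sd_iou))
  cat(sprintf("  lateral  %.4f +/- %.4f (|ratio|)\n",
              s$mean_abs_lateral, s$sd_abs_lateral))
  cat(sprintf("  angular  %.2f +/- %.2f deg\n",
              s$mean_angular_deg, s$sd_angular_deg))
  invisible(x)
}

#' Segmenter closure for a fitted model
#'
#' @param model trained `crop_cnn`.
#' @param method "cam" (CAM segmentation) or "ipc" (80-px patch tiling).
#' @param ... extra arguments for [segment_crop_area()] /
#'   [segment_by_patches()].
#' @return function(image) -> `crop_segmentation`.
#' @export
make_segmenter <- function(model, method = c("cam", "ipc"), ...) {
  method <- match.arg(method)
  if (method == "cam") function(image) segment_crop_area(image, model, ...)
  else function(image) segment_by_patches(image, model, ...)
}
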