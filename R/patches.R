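# Class-specific cropping: the only supervision the method uses is an
# image-level label on a class-pure sub-image. One patch per class per
# frame; patches alternate frame-wise into train/validation halves.

# Purity demanded of a patch window, per class. The crop boundary is ragged
# in real imagery, so the crop class tolerates 5% foreign pixels; background
# and harvested windows must be pure.
purity_threshold_for <- function(class_id) if (class_id == 1L) 0.95 else 1.0

# Integral image (summed-area table) with a zero top row/left column, so
# window sums are O(1): S[y1+1,x1+1] - S[y0,x1+1] - S[y1+1,x0] + S[y0,x0].
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

window_sum <- function(S, y0, x0, h, w) {
  S[y0 + h + 1, x0 + w + 1] - S[y0 + 1, x0 + w + 1] -
    S[y0 + h + 1, x0 + 1] + S[y0 + 1, x0 + 1]
}

#' Extract the class-specific patch of one scene
#'
#' Finds a maximal axis-aligned window of the requested class: the exact
#' largest fully-pure rectangle (ties broken topmost-then-leftmost). When
#' that rectangle is smaller than `min_size` on an axis and the class
#' tolerates impurity (crop, whose boundary is ragged), a deterministic
#' greedy 1-px expansion (top, bottom, left, right, repeated) grows the
#' window while its purity stays at or above the class threshold. The
#' returned window is at least `min_size` on both axes so a `min_size`
#' random crop is always possible.
#'
#' @param sample a `scene_sample`.
#' @param class_id class label 0 (background), 1 (crop) or 2 (harvested).
#' @param min_size minimum admissible window side, pixels.
#' @param purity_threshold minimum fraction of window pixels carrying
#'   `class_id`; default 1.0 for background/harvested, 0.95 for crop.
#' @return object of class `labeled_patch`: list with `pixels` (h x w x 3),
#'   `label`, `source_frame`, `purity`, and window origin/size `x0`, `y0`
#'   (0-based), `w`, `h`.
#' @export
crop_class_region <- function(sample, class_id, min_size = 64,
                              purity_threshold = NULL) {
  stopifnot(class_id %in% 0:2)
  thr <- purity_threshold %||% purity_threshold_for(class_id)
  b <- matrix(as.integer(sample$mask == class_id), nrow(sample$mask))
  r <- cc_largest_rect(b, min_size, min_size)
  if (r[1] < 0) {
    # no pure window of admissible size; fall back to the largest pure
    # core anywhere (the ragged-boundary rescue below may still grow it)
    r <- cc_largest_rect(b)
    if (r[1] < 0 || thr >= 1)
      stop_with("noRegionError",
                "no admissible %s window of side >= %d at purity %.2f",
                CLASS_NAMES[class_id + 1L], min_size, thr)
  }
  y0 <- r[1]; x0 <- r[2]; h <- r[3]; w <- r[4]
  H <- nrow(b); W <- ncol(b)
  S <- integral_image(b)
  if ((h < min_size || w < min_size) && thr < 1) {
    # ragged-boundary rescue: grow the pure core 1 px at a time while the
    # window keeps the relaxed purity (deterministic direction order)
    pure_enough <- function(y0, x0, h, w)
      window_sum(S, y0, x0, h, w) >= thr * h * w
    repeat {
      grew <- FALSE
      if (y0 > 0 && pure_enough(y0 - 1, x0, h + 1, w)) {
        y0 <- y0 - 1; h <- h + 1; grew <- TRUE
      }
      if (y0 + h < H && pure_enough(y0, x0, h + 1, w)) {
        h <- h + 1; grew <- TRUE
      }
      if (x0 > 0 && pure_enough(y0, x0 - 1, h, w + 1)) {
        x0 <- x0 - 1; w <- w + 1; grew <- TRUE
      }
      if (x0 + w < W && pure_enough(y0, x0, h, w + 1)) {
        w <- w + 1; grew <- TRUE
      }
      if (!grew) break
    }
  }
  if (h < min_size || w < min_size)
    stop_with("noRegionError",
              "no admissible %s window of side >= %d at purity %.2f",
              CLASS_NAMES[class_id + 1L], min_size, thr)
  purity <- window_sum(S, y0, x0, h, w) / (h * w)
  structure(list(pixels = sample$image[(y0 + 1):(y0 + h),
                                       (x0 + 1):(x0 + w), , drop = FALSE],
                 label = as.integer(class_id),
                 source_frame = sample$frame_id,
                 purity = purity, x0 = x0, y0 = y0, w = w, h = h),
            class = "labeled_patch")
}

#' Build the labeled patch dataset from a list of scenes
#'
#' One patch per class per frame; frames where any class lacks an
#' admissible window are skipped and reported. Frames alternate into the
#' train/validation halves by frame index (even to train, odd to
#' validation), a deterministic realization of a half/half split.
#'
#' @param samples list of `scene_sample`.
#' @param min_size minimum patch side (also the training crop size), px.
#' @return object of class `patch_split`: list with `train` and `val`
#'   (lists of `labeled_patch`), `skipped` (data.frame frame/reason), and
#'   `crop_size`.
#' @export
build_patch_dataset <- function(samples, min_size = 64) {
  train <- list(); val <- list()
  skipped <- data.frame(frame = integer(), reason = character())
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fid <- if (is.na(s$frame_id)) i - 1L else s$frame_id
    patches <- tryCatch(
      lapply(0:2, function(cl) {
        p <- crop_class_region(s, cl, min_size = min_size)
        p$source_frame <- fid
        p
      }),
      noRegionError = function(e) e)
    if (inherits(patches, "error")) {
      skipped <- rbind(skipped,
                       data.frame(frame = fid, reason = conditionMessage(patches)))
      next
    }
    if (fid %% 2L == 0L) train <- c(train, patches)
    else val <- c(val, patches)
  }
  if (nrow(skipped) > 0)
    message(sprintf("build_patch_dataset: skipped %d frame(s): %s",
                    nrow(skipped), paste(skipped$frame, collapse = ", ")))
  structure(list(train = train, val = val, skipped = skipped,
                 crop_size = min_size),
            class = "patch_split")
}

#' @export
print.patch_split <- function(x, ...) {
  tab <- function(l) table(factor(vapply(l, `[[`, 0L, "label"), levels = 0:2))
  cat(sprintf("patch split: %d train / %d val (crop size %d)\n",
              length(x$train), length(x$val), x$crop_size))
  cat("  train per class:", paste(tab(x$train), collapse = "/"),
      " val per class:", paste(tab(x$val), collapse = "/"), "\n")
  if (nrow(x$skipped)) cat("  skipped frames:", nrow(x$skipped), "\n")
  invisible(x)
}

#' Random square crop of a patch
#'
#' Uniformly random admissible origin; deterministic under `seed`.
#'
#' @param patch a `labeled_patch` (or any list with a `pixels` array).
#' @param crop_size side of the square crop, pixels.
#' @param seed integer seed; when NULL the current RNG stream is used (as
#'   inside the training loop).
#' @return `crop_size` x `crop_size` x 3 array.
#' @export
random_crop_view <- function(patch, crop_size, seed = NULL) {
  d <- dim(patch$pixels)
  if (d[1] < crop_size || d[2] < crop_size)
    stop("patch (", d[1], "x", d[2], ") smaller than crop_size ", crop_size)
  draw <- function() {
    y0 <- sample.int(d[1] - crop_size + 1L, 1L)
    x0 <- sample.int(d[2] - crop_size + 1L, 1L)
    patch$pixels[y0:(y0 + crop_size - 1L), x0:(x0 + crop_size - 1L), ,
                 drop = FALSE]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# deterministic central crop, used for validation
center_crop_view <- function(patch, crop_size) {
  d <- dim(patch$pixels)
  if (d[1] < crop_size || d[2] < crop_size)
    stop("patch smaller than crop_size")
  y0 <- (d[1] - crop_size) %/% 2L + 1L
  x0 <- (d[2] - crop_size) %/% 2L + 1L
  patch$pixels[y0:(y0 + crop_size - 1L), x0:(x0 + crop_size - 1L), ,
               drop = FALSE]
}

#' Patch manifest as a data frame
#'
#' @param split a `patch_split`.
#' @return data.frame with patch_id, source_frame, label, x0, y0, w, h,
#'   purity, split.
#' @export
patch_manifest <- function(split) {
  row1 <- function(p, sp)
    data.frame(source_frame = p$source_frame, label = p$label,
               x0 = p$x0, y0 = p$y0, w = p$w, h = p$h,
               purity = p$purity, split = sp)
  df <- rbind(do.call(rbind, lapply(split$train, row1, sp = "train")),
              do.call(rbind, lapply(split$val, row1, sp = "val")))
  if (is.null(df)) return(data.frame())
  df <- cbind(patch_id = seq_len(nrow(df)) - 1L, df)
  df
}
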