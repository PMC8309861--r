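# On-disk artifacts and the end-to-end pipeline. Scene bundles use the
# layout frames/NNNN.png, masks/NNNN.png, gt/NNNN.json. Mask PNG dialects:
# ground-truth masks are single-channel 8-bit PNGs with literal levels
# 0/1/2; binary prediction masks use levels 0/255.

frame_name <- function(i) sprintf("%04d", i)

#' Write an image array as PNG
#' @param img H x W x 3 integer array, 0-255.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a PNG image to a 0-255 integer array
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3]  # drop alpha
  array(as.integer(round(a * 255)), dim(a))
}

#' Write a label or binary mask as single-channel PNG
#' @param mask integer matrix; labels 0/1/2 (`dialect = "labels"`) or 0/1
#'   written as 0/255 (`dialect = "binary"`).
#' @param path output path.
#' @param dialect mask encoding.
#' @export
write_mask_png <- function(mask, path, dialect = c("labels", "binary")) {
  dialect <- match.arg(dialect)
  v <- if (dialect == "labels") mask / 255 else (mask != 0) * 1
  png::writePNG(matrix(v, nrow(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, dialect = c("labels", "binary")) {
  dialect <- match.arg(dialect)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  if (dialect == "labels") matrix(as.integer(round(a * 255)), nrow(a))
  else matrix(as.integer(a > 0.5), nrow(a))
}

#' Write a list of scenes as a bundle directory
#'
#' @param samples list of `scene_sample`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(samples, dir) {
  for (sub in c("frames", "masks", "gt"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fid <- if (is.na(s$frame_id)) i - 1L else s$frame_id
    nm <- frame_name(fid)
    write_image_png(s$image, file.path(dir, "frames", paste0(nm, ".png")))
    write_mask_png(s$mask, file.path(dir, "masks", paste0(nm, ".png")))
    gt <- list(edge = list(rho = s$gt_edge$rho,
                           theta_deg = s$gt_edge$theta_deg),
               polygon = unname(apply(s$gt_polygon, 1, as.numeric,
                                      simplify = FALSE)),
               spec = s$spec[c("width", "height", "horizon_row",
                               "edge_bottom_x", "edge_angle_deg",
                               "noise_sigma", "seed")],
               frame_id = fid)
    jsonlite::write_json(gt, file.path(dir, "gt", paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a scene bundle directory
#'
#' @param dir bundle directory written by [write_scene_bundle()].
#' @return list of `scene_sample` in frame order (images, masks, ground
#'   truth restored; texture parameters are not stored and come back as
#'   defaults).
#' @export
read_scene_bundle <- function(dir) {
  frames <- sort(list.files(file.path(dir, "frames"), pattern = "\\.png$"))
  masks <- sort(list.files(file.path(dir, "masks"), pattern = "\\.png$"))
  if (!identical(frames, masks)) {
    miss <- c(setdiff(frames, masks), setdiff(masks, frames))
    stop("frame/mask mismatch for: ", paste(miss, collapse = ", "))
  }
  lapply(frames, function(f) {
    nm <- sub("\\.png$", "", f)
    img <- read_image_png(file.path(dir, "frames", f))
    mask <- read_mask_png(file.path(dir, "masks", f))
    gt <- jsonlite::read_json(file.path(dir, "gt", paste0(nm, ".json")),
                              simplifyVector = TRUE)
    spec <- scene_spec(width = gt$spec$width, height = gt$spec$height,
                       horizon_row = gt$spec$horizon_row,
                       edge_bottom_x = gt$spec$edge_bottom_x,
                       edge_angle_deg = gt$spec$edge_angle_deg,
                       noise_sigma = gt$spec$noise_sigma,
                       seed = gt$spec$seed)
    structure(list(image = img, mask = mask,
                   gt_edge = edge_line(gt$edge$rho, gt$edge$theta_deg,
                                       gt$spec$height),
                   gt_polygon = if (is.matrix(gt$polygon)) gt$polygon
                                else matrix(unlist(gt$polygon), ncol = 2,
                                            byrow = TRUE),
                   spec = spec, frame_id = gt$frame_id %||% NA_integer_),
              class = "scene_sample")
  })
}

#' Default end-to-end run configuration
#'
#' Desk-scale study conditions: an 80-frame synthetic harvest sequence of
#' 180 x 180 scenes whose crop edge drifts left and rotates slowly; the
#' first 60 frames train the classifier (64-px patch crops), the last 20
#' are held out for evaluation; inference runs at 176 px.
#'
#' @param seed global seed; all stage seeds derive from it.
#' @return nested configuration list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(width = 180L, height = 180L, horizon_row = 68L,
                 edge_bottom_x = 118, edge_angle_deg = -6,
                 noise_sigma = 6),
    sequence = list(n_frames = 80L, drift_x = -0.45, drift_angle = 0.15,
                    n_train = 60L),
    dataset = list(crop_size = 64L),
    train = list(learning_rate = 1e-4, batch_size = 64L, patience = 8L,
                 max_epochs = 40L),
    segment = list(infer_size = 176L, min_area_frac = 0.005),
    edge = list(trim_fraction = 0.10),
    methods = c("cam", "ipc"),
    ipc = list(patch_size = 80L)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config())
  for (nm in names(cfg)) {
    if (is.list(base[[nm]])) base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    else base[[nm]] <- cfg[[nm]]
  }
  structure(base, class = "run_config")
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline
#'
#' generate -> build dataset -> train -> segment -> detect edge -> evaluate,
#' with every stage seeded from the single global seed. When `out` is given,
#' artifacts (scene bundle, checkpoint, per-frame and summary CSVs, config
#' and manifest) are written there; reruns with the same configuration
#' reproduce the report exactly.
#'
#' @param config a `run_config`.
#' @param out optional artifact directory.
#' @param verbose log stage progress.
#' @return list with `model`, `evals` (one `edge_eval` per method),
#'   `frames` and `summary` data.frames, and `n_train`/`n_test`.
#' @export
run_pipeline <- function(config = default_run_config(), out = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sc <- config$scene; sq <- config$sequence
  say("stage generate: %d frames of %dx%d", sq$n_frames, sc$width, sc$height)
  spec0 <- scene_spec(width = sc$width, height = sc$height,
                      horizon_row = sc$horizon_row,
                      edge_bottom_x = sc$edge_bottom_x,
                      edge_angle_deg = sc$edge_angle_deg,
                      noise_sigma = sc$noise_sigma,
                      seed = sub_seed(config$seed, "scenes"))
  seqs <- generate_sequence(sq$n_frames, spec0,
                            drift = list(edge_bottom_x = sq$drift_x,
                                         edge_angle_deg = sq$drift_angle))
  if (length(seqs) < sq$n_frames)
    stop("stage generate: drift truncated the sequence to ", length(seqs),
         " frames")
  train_scenes <- seqs[seq_len(sq$n_train)]
  test_scenes <- seqs[(sq$n_train + 1L):length(seqs)]

  say("stage build-dataset: crop size %d", config$dataset$crop_size)
  split <- build_patch_dataset(train_scenes,
                               min_size = config$dataset$crop_size)

  say("stage train: up to %d epochs", config$train$max_epochs)
  model <- fit_crop_classifier(
    split,
    backbone = backbone_config(input_size = config$dataset$crop_size),
    config = train_config(learning_rate = config$train$learning_rate,
                          batch_size = config$train$batch_size,
                          patience = config$train$patience,
                          max_epochs = config$train$max_epochs,
                          seed = config$seed),
    verbose = verbose)

  say("stage evaluate: %d held-out frames", length(test_scenes))
  min_area <- ceiling(config$segment$min_area_frac * sc$width * sc$height)
  evals <- list()
  for (m in config$methods) {
    seg_fun <- if (m == "cam")
      make_segmenter(model, "cam", infer_size = config$segment$infer_size,
                     min_area = min_area)
    else make_segmenter(model, "ipc", patch_size = config$ipc$patch_size)
    evals[[m]] <- evaluate_run(test_scenes, seg_fun, method = m,
                               trim_fraction = config$edge$trim_fraction)
  }
  frames <- do.call(rbind, lapply(evals, `[[`, "frames"))
  rownames(frames) <- NULL
  summary <- do.call(rbind, lapply(evals, `[[`, "summary"))
  rownames(summary) <- NULL

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_scene_bundle(seqs, file.path(out, "scenes"))
    save_crop_cnn(model, file.path(out, "model.ckpt"))
    write.csv(frames, file.path(out, "frame_metrics.csv"), row.names = FALSE)
    write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)
    write.csv(patch_manifest(split), file.path(out, "patches.csv"),
              row.names = FALSE)
    cfg_path <- file.path(out, "config.yaml")
    write_run_config(config, cfg_path)
    manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = config$seed,
                     version = as.character(utils::packageVersion("cropcam")))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(model = model, evals = evals, frames = frames, summary = summary,
       n_train = length(train_scenes), n_test = length(test_scenes))
}
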