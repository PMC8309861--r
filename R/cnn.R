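# The shallow classification backbone: four 3x3 stride-1 same-padding
# convolution blocks with ReLU, 2x2 max-pooling after blocks 1-3 (total
# output stride 8), ending in 256 feature maps; a global-average-pooling
# head connects the 256 map scores to the 3 class logits with a bias-free
# weight matrix, so the same weights that classify also generate class
# activation maps.

#' Backbone architecture configuration
#'
#' @param conv_channels output channels of the four conv blocks; the last
#'   entry must be 256 (the number of final feature maps).
#' @param kernel_size convolution kernel side; fixed at 3 in this
#'   implementation.
#' @param pool_after logical(4): which blocks are followed by 2x2
#'   max-pooling; exactly three must be, giving output stride 8 (each final
#'   map is 1/8 of the input size).
#' @param input_size training input side in pixels; must be divisible by 8.
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(conv_channels = c(32, 64, 128, 256),
                            kernel_size = 3,
                            pool_after = c(TRUE, TRUE, TRUE, FALSE),
                            input_size = 360) {
  stopifnot(length(conv_channels) == 4, length(pool_after) == 4)
  if (conv_channels[4] != 256)
    stop("the final conv block must produce 256 feature maps")
  if (sum(pool_after) != 3)
    stop("exactly 3 of the 4 blocks must pool (output stride 8)")
  if (kernel_size != 3)
    stop("only 3x3 kernels are implemented")
  if (input_size %% 8 != 0)
    stop("input_size must be divisible by 8 (output stride is 8)")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = 3L, pool_after = pool_after,
                 input_size = as.integer(input_size), n_classes = 3L),
            class = "backbone_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param patience epochs without a new minimum validation loss before
#'   training halts (early termination at the lowest validation cost).
#' @param max_epochs hard epoch cap.
#' @param seed RNG seed governing weight init, shuffling and crop draws.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64,
                         patience = 10, max_epochs = 200, seed = 1L) {
  stopifnot(patience >= 1, batch_size >= 1, max_epochs >= 1,
            learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Kaiming fan-in scaled init for conv weights ((Cin*9) x Cout matrices),
# small-variance zero-mean for the bias-free head.
init_weights <- function(backbone, seed) {
  with_seed(seed, {
    cin <- 3L
    conv <- vector("list", 4L)
    for (l in 1:4) {
      cout <- backbone$conv_channels[l]
      fan_in <- cin * 9L
      conv[[l]] <- list(
        w = matrix(rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout),
        b = rep(0, cout))
      cin <- cout
    }
    head <- matrix(rnorm(backbone$n_classes * 256, 0, 0.01),
                   backbone$n_classes, 256)
    list(conv = conv, head = head)
  })
}

# images enter the net as centred [-0.5, 0.5] reals
normalize_image <- function(img) img / 255 - 0.5

# Forward pass through the conv backbone. x: H x W x 3 normalized array.
# Returns the final feature maps (h/8 x w/8 x 256) and, when keep_cache,
# everything backward needs.
cnn_forward <- function(weights, x, backbone, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", 4L) else NULL
  for (l in 1:4) {
    cv <- cc_conv2d_fwd(x, weights$conv[[l]]$w, weights$conv[[l]]$b,
                        keep_cache)
    a <- cv$out
    relu_mask <- a > 0
    a[!relu_mask] <- 0
    if (backbone$pool_after[l]) {
      pl <- cc_maxpool2_fwd(a, keep_cache)
      if (keep_cache)
        cache[[l]] <- list(xcol = cv$xcol, relu = relu_mask,
                           pool_idx = pl$idx, pre_pool_dim = dim(a))
      x <- pl$out
    } else {
      if (keep_cache)
        cache[[l]] <- list(xcol = cv$xcol, relu = relu_mask,
                           pool_idx = NULL, pre_pool_dim = dim(a))
      x <- a
    }
  }
  list(maps = x, cache = cache)
}

# Backward pass given d(loss)/d(maps); returns gradients for all conv
# weights plus nothing for the head (handled by the caller).
cnn_backward <- function(weights, cache, dmaps, backbone) {
  grads <- vector("list", 4L)
  dy <- dmaps
  for (l in 4:1) {
    cc <- cache[[l]]
    if (backbone$pool_after[l])
      dy <- cc_maxpool2_bwd(dy, cc$pool_idx,
                            cc$pre_pool_dim[1], cc$pre_pool_dim[2])
    dy[!cc$relu] <- 0
    cin <- if (l == 1) 3L else backbone$conv_channels[l - 1]
    bk <- cc_conv2d_bwd(dy, cc$xcol, weights$conv[[l]]$w, cin)
    grads[[l]] <- list(w = bk$dw, b = bk$db)
    dy <- bk$dx
  }
  grads
}

#' Global average pooling of feature maps
#'
#' Reduces each feature map to its exact arithmetic mean over pixels: the
#' 256 map scores that feed the classification head.
#'
#' @param maps h x w x K array of (post-ReLU) feature maps.
#' @return numeric vector of K map means.
#' @export
global_average_pool <- function(maps) {
  d <- dim(maps)
  if (is.null(d) || length(d) != 3L || d[1] * d[2] < 1)
    stop("maps must be a non-empty h x w x K array")
  colMeans(matrix(maps, d[1] * d[2], d[3]))
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Class probabilities for one image
#'
#' Runs the backbone, pools the final feature maps, and applies the
#' bias-free head followed by a softmax over the three classes.
#'
#' @param image H x W x 3 array on the 0-255 scale; both sides must be
#'   divisible by 8.
#' @param model a `crop_cnn` (see [fit_crop_classifier()]) or a raw
#'   weights/backbone list.
#' @return numeric(3) probability vector named background/crop/harvested.
#' @export
classify <- function(image, model) {
  d <- dim(image)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("image sides must be divisible by 8, got ", d[1], "x", d[2])
  fw <- cnn_forward(model$weights, normalize_image(image), model$backbone)
  g <- global_average_pool(fw$maps)
  if (ncol(model$weights$head) != length(g))
    stop("head width ", ncol(model$weights$head),
         " does not match ", length(g), " feature maps")
  p <- softmax(as.numeric(model$weights$head %*% g))
  names(p) <- CLASS_NAMES
  p
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(weights) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_update <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

# one-hot target for label in 0:2
one_hot <- function(label, n = 3L) {
  t <- numeric(n); t[label + 1L] <- 1; t
}

# forward + loss + gradients for a single image; MSE between the softmax
# probability vector and the one-hot target.
train_step_single <- function(weights, img, label, backbone) {
  fw <- cnn_forward(weights, normalize_image(img), backbone, keep_cache = TRUE)
  d <- dim(fw$maps); n_pix <- d[1] * d[2]
  g <- global_average_pool(fw$maps)
  z <- as.numeric(weights$head %*% g)
  p <- softmax(z)
  t <- one_hot(label)
  loss <- mean((p - t)^2)
  dldp <- 2 * (p - t) / length(p)
  dz <- p * (dldp - sum(dldp * p))          # softmax jacobian product
  dhead <- outer(dz, g)
  dg <- as.numeric(crossprod(weights$head, dz))
  dmaps <- array(rep(dg / n_pix, each = n_pix), d)
  conv_grads <- cnn_backward(weights, fw$cache, dmaps, backbone)
  list(loss = loss, correct = (which.max(p) - 1L) == label,
       grads = list(conv = conv_grads, head = dhead))
}

eval_loss <- function(weights, views, labels, backbone) {
  losses <- numeric(length(views)); correct <- logical(length(views))
  for (i in seq_along(views)) {
    fw <- cnn_forward(weights, normalize_image(views[[i]]), backbone)
    p <- softmax(as.numeric(weights$head %*% global_average_pool(fw$maps)))
    losses[i] <- mean((p - one_hot(labels[i]))^2)
    correct[i] <- (which.max(p) - 1L) == labels[i]
  }
  list(loss = mean(losses), acc = mean(correct))
}

#' Fit the patch classifier
#'
#' Trains the 4-layer backbone + GAP head as a 3-class classifier of
#' labeled patches: random square crops of each training patch enter the
#' net each epoch, the loss is the mean squared error between the softmax
#' output and the one-hot label, updates use Adam, and training halts when
#' the validation loss (on deterministic centre crops) has not improved for
#' `config$patience` epochs. The returned weights are those of the epoch
#' with minimum validation loss.
#'
#' @param split a `patch_split` from [build_patch_dataset()]; both halves
#'   must be non-empty and contain every class.
#' @param backbone a [backbone_config()]; its `input_size` is the training
#'   crop size.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @return object of class `crop_cnn`: list with `weights`, `backbone`,
#'   `history` (per-epoch data.frame), `best_epoch`, `classes`.
#' @export
fit_crop_classifier <- function(split, backbone = backbone_config(),
                                config = train_config(), verbose = FALSE) {
  labs_tr <- vapply(split$train, `[[`, 0L, "label")
  labs_va <- vapply(split$val, `[[`, 0L, "label")
  if (length(labs_tr) == 0 || length(labs_va) == 0)
    stop("both split halves must be non-empty")
  if (!all(0:2 %in% labs_tr) || !all(0:2 %in% labs_va))
    stop("both split halves must contain every class")
  cs <- backbone$input_size
  weights <- init_weights(backbone, sub_seed(config$seed, "init"))
  opt <- adam_init(weights)
  val_views <- lapply(split$val, center_crop_view, crop_size = cs)

  history <- data.frame(epoch = integer(), train_loss = double(),
                        val_loss = double(), val_acc = double())
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  since_best <- 0L

  with_seed(sub_seed(config$seed, "shuffle"), {
    n <- length(split$train)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      done <- 0L
      while (done < n) {
        idx <- ord[(done + 1L):min(done + config$batch_size, n)]
        acc_g <- NULL
        bloss <- 0
        for (i in idx) {
          view <- random_crop_view(split$train[[i]], cs)
          st <- train_step_single(weights, view, labs_tr[i], backbone)
          bloss <- bloss + st$loss
          acc_g <- if (is.null(acc_g)) st$grads else
            accumulate_grads(acc_g, st$grads)
        }
        k <- length(idx)
        opt$t <- opt$t + 1L
        for (l in 1:4) {
          for (nm in c("w", "b")) {
            up <- adam_update(weights$conv[[l]][[nm]],
                              acc_g$conv[[l]][[nm]] / k,
                              opt$m$conv[[l]][[nm]], opt$v$conv[[l]][[nm]],
                              config$learning_rate, opt$t)
            weights$conv[[l]][[nm]] <- up$w
            opt$m$conv[[l]][[nm]] <- up$m
            opt$v$conv[[l]][[nm]] <- up$v
          }
        }
        up <- adam_update(weights$head, acc_g$head / k, opt$m$head,
                          opt$v$head, config$learning_rate, opt$t)
        weights$head <- up$w; opt$m$head <- up$m; opt$v$head <- up$v
        epoch_loss <- epoch_loss + bloss
        done <- done + k
      }
      ev <- eval_loss(weights, val_views, labs_va, backbone)
      if (!is.finite(ev$loss) || !is.finite(epoch_loss))
        stop("training diverged: non-finite loss at epoch ", epoch)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = epoch_loss / n,
                                  val_loss = ev$loss, val_acc = ev$acc))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  acc %.3f",
                        epoch, epoch_loss / n, ev$loss, ev$acc))
      if (ev$loss < best$loss) {
        best <- list(loss = ev$loss, weights = weights, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })

  structure(list(weights = best$weights, backbone = backbone,
                 config = config, history = history,
                 best_epoch = best$epoch, classes = CLASS_NAMES,
                 trained = TRUE),
            class = "crop_cnn")
}

accumulate_grads <- function(a, b) {
  for (l in 1:4) {
    a$conv[[l]]$w <- a$conv[[l]]$w + b$conv[[l]]$w
    a$conv[[l]]$b <- a$conv[[l]]$b + b$conv[[l]]$b
  }
  a$head <- a$head + b$head
  a
}

#' Construct an untrained model from a backbone configuration
#'
#' Useful for forward-shape checks and for plugging in hand-set (oracle)
#' weights.
#'
#' @param backbone a [backbone_config()].
#' @param seed init seed.
#' @return `crop_cnn` with `trained = FALSE`.
#' @export
build_model <- function(backbone = backbone_config(), seed = 1L) {
  structure(list(weights = init_weights(backbone, seed),
                 backbone = backbone, config = NULL,
                 history = NULL, best_epoch = NA_integer_,
                 classes = CLASS_NAMES, trained = FALSE),
            class = "crop_cnn")
}

#' Final feature maps of an image
#'
#' @param image H x W x 3 array, 0-255 scale, sides divisible by 8.
#' @param model a `crop_cnn`.
#' @return (H/8) x (W/8) x 256 array of post-ReLU activations.
#' @export
forward_features <- function(image, model) {
  d <- dim(image)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("image sides must be divisible by 8, got ", d[1], "x", d[2])
  cnn_forward(model$weights, normalize_image(image), model$backbone)$maps
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.crop_cnn <- function(x, ...) {
  cat("crop-area patch classifier (4-layer CNN + GAP head)\n")
  cat(sprintf("  channels %s, input %d, final maps %d x %d x 256\n",
              paste(x$backbone$conv_channels, collapse = "-"),
              x$backbone$input_size,
              x$backbone$input_size / 8, x$backbone$input_size / 8))
  if (isTRUE(x$trained))
    cat(sprintf("  trained: %d epochs, best val loss %.5f (epoch %d), val acc %.3f\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch,
                x$history$val_acc[x$best_epoch]))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.crop_cnn <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$weights$conv,
                   function(l) length(l$w) + length(l$b), 0)) +
    length(object$weights$head)
  cat(sprintf("  parameters: %d\n", np))
  if (!is.null(object$history)) {
    cat("  last epochs:\n")
    print(tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Head weights of the GAP classifier
#'
#' The 3 x 256 bias-free weight matrix connecting map scores to class
#' logits -- the same weights that build the class activation maps.
#' @param object a `crop_cnn`.
#' @param ... unused.
#' @export
coef.crop_cnn <- function(object, ...) {
  w <- object$weights$head
  rownames(w) <- CLASS_NAMES
  w
}

#' Predict from a fitted patch classifier
#'
#' @param object a `crop_cnn`.
#' @param image H x W x 3 array, 0-255 scale.
#' @param type "prob" (class probabilities), "class" (label id 0/1/2),
#'   "features" (final feature maps), "cams" (class activation maps) or
#'   "segmentation" (full crop-area segmentation of the scene).
#' @param ... passed to [segment_crop_area()] for type = "segmentation".
#' @export
predict.crop_cnn <- function(object, image,
                             type = c("prob", "class", "features", "cams",
                                      "segmentation"), ...) {
  type <- match.arg(type)
  switch(type,
    prob = classify(image, object),
    class = unname(which.max(classify(image, object))) - 1L,
    features = forward_features(image, object),
    cams = compute_cams(forward_features(image, object),
                        object$weights$head),
    segmentation = segment_crop_area(image, object, ...))
}

#' Plot the training history
#'
#' @param x a trained `crop_cnn`.
#' @param ... unused.
#' @export
plot.crop_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0) stop("model has no training history")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "MSE loss",
       ylim = range(c(h$train_loss, h$val_loss)))
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding all weight arrays, the
#' backbone configuration and the training history; loading restores
#' bit-identical inference.
#' @param model a `crop_cnn`.
#' @param path file path.
#' @export
save_crop_cnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_crop_cnn
#' @export
load_crop_cnn <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "crop_cnn")) stop("not a crop_cnn checkpoint: ", path)
  m
}
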