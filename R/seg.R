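# U-Net eyelid-region segmentation: R-side configuration, initialization,
# SGD training loop with early stopping, and inference. The compiled engine
# (src/unet.cpp) does the forward/backward passes.

#' Training configuration for the segmentation network
#'
#' @param input_size Square side (pixels) images and masks are resized to
#'   with nearest-neighbour interpolation before training/inference. Must be
#'   divisible by 16 (four 2x2 poolings).
#' @param base_width Channels of the first encoder level; doubled at each of
#'   the four downsampling steps. 64 matches the classic U-Net; 16 is
#'   enough for the synthetic eye task and much faster on a CPU.
#' @param lr,momentum SGD learning rate and momentum.
#' @param lr_step,lr_gamma Decay the learning rate by `lr_gamma` every
#'   `lr_step` epochs.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param patience Early-stopping patience: stop when the validation Dice
#'   coefficient has not improved for this many consecutive epochs.
#' @param split Train/validation/test proportions (largest-remainder
#'   rounding; see [split_indices()]).
#' @param augment Random horizontal/vertical flips on the training split.
#' @param threshold Probability cut-off turning the network output into a
#'   binary mask.
#' @param seed Seed driving the split, weight init, shuffling and
#'   augmentation.
#' @return A list of class `"seg_config"`.
#' @export
seg_config <- function(input_size = 512L, base_width = 64L, lr = 0.01,
                       momentum = 0.9, lr_step = 20L, lr_gamma = 0.1,
                       epochs = 100L, batch_size = 4L, patience = 20L,
                       split = c(8, 1, 1) / 10, augment = TRUE,
                       threshold = 0.5, seed = 1L) {
  if (input_size %% 16 != 0) stopf("input_size must be divisible by 16")
  if (base_width < 1 || lr <= 0 || momentum < 0 || epochs < 1 ||
      batch_size < 1)
    stopf("all training parameters must be positive")
  if (patience > epochs) stopf("patience must not exceed epochs")
  structure(list(input_size = as.integer(input_size),
                 base_width = as.integer(base_width), lr = lr,
                 momentum = momentum, lr_step = as.integer(lr_step),
                 lr_gamma = lr_gamma, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), split = split,
                 augment = isTRUE(augment), threshold = threshold,
                 seed = as.integer(seed)),
            class = "seg_config")
}

# conv layer order expected by the compiled engine
unet_layer_dims <- function(base_width) {
  B <- base_width
  ch <- B * c(1L, 2L, 4L, 8L, 16L)
  dims <- list()
  cin <- 1L
  for (d in 1:4) {                     # encoder
    dims[[length(dims) + 1L]] <- c(ch[d], cin)
    dims[[length(dims) + 1L]] <- c(ch[d], ch[d])
    cin <- ch[d]
  }
  dims[[length(dims) + 1L]] <- c(ch[5], ch[4])   # bottleneck
  dims[[length(dims) + 1L]] <- c(ch[5], ch[5])
  cin <- ch[5]
  for (d in 4:1) {                     # decoder (after skip concat)
    dims[[length(dims) + 1L]] <- c(ch[d], cin + ch[d])
    dims[[length(dims) + 1L]] <- c(ch[d], ch[d])
    cin <- ch[d]
  }
  dims[[length(dims) + 1L]] <- c(1L, ch[1])      # final 1x1
  dims
}

# He-initialized weights in the engine's flat layout: each 3x3 conv
# contributes [W, instance-norm gamma, instance-norm beta], the final 1x1
# classifier [W, bias].
unet_init_weights <- function(base_width) {
  dims <- unet_layer_dims(base_width)
  nlay <- length(dims)
  w <- list()
  for (l in seq_len(nlay)) {
    cout <- dims[[l]][1]; cin <- dims[[l]][2]
    k2 <- if (l == nlay) 1L else 9L    # final layer is 1x1
    fan_in <- cin * k2
    w[[length(w) + 1L]] <- matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)),
                                  cout, cin * k2)
    if (l < nlay) {
      w[[length(w) + 1L]] <- rep(1, cout)    # gamma
      w[[length(w) + 1L]] <- numeric(cout)   # beta
    } else {
      w[[length(w) + 1L]] <- numeric(cout)   # bias
    }
  }
  w
}

#' Nearest-neighbour resize of a matrix
#'
#' @param m Numeric matrix.
#' @param h,w Target size in pixels.
#' @return Resized matrix.
#' @export
resize_nn <- function(m, h, w) {
  ri <- pmin(nrow(m), floor((seq_len(h) - 0.5) * nrow(m) / h) + 1L)
  ci <- pmin(ncol(m), floor((seq_len(w) - 0.5) * ncol(m) / w) + 1L)
  m[ri, ci, drop = FALSE]
}

#' Train the eyelid-region segmentation network
#'
#' Fits a four-level U-Net (two 3x3 convolutions + 2x2 max-pool per encoder
#' level with channel doubling; mirrored decoder with 2x2 nearest-neighbour
#' upsampling and skip concatenation; final 1x1 per-pixel classifier) with
#' the soft Dice loss and SGD with momentum. The checkpoint with the best
#' validation Dice coefficient is returned; training stops early when the
#' validation Dice has not improved for `config$patience` epochs.
#'
#' @param frames List of grayscale images (matrices in `[0, 1]`).
#' @param masks List of matching binary masks.
#' @param config A [seg_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `"blink_unet"`: the best weights, the config,
#'   the data split, and `history` (data frame of epoch, train_loss,
#'   val_dsc).
#' @examples
#' \donttest{
#' spec <- synth_spec(duration_s = 1, fps = 8, image_w = 96, image_h = 96,
#'                    max_aperture_frac = 0.45, baseline_iph_frac = 0.35)
#' vid <- synthesize_video(spec)
#' fit <- train_segmentation(vid$frames, vid$masks,
#'                           seg_config(input_size = 32, base_width = 4,
#'                                      epochs = 2, patience = 2))
#' fit$history
#' }
#' @export
train_segmentation <- function(frames, masks, config = seg_config(),
                               verbose = FALSE) {
  if (length(frames) == 0) stopf("empty training dataset")
  if (length(frames) != length(masks))
    stopf("frames and masks must have equal length")
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), dim(masks[[i]])))
      stopf("frame/mask shape mismatch at index %d", i)
  S <- config$input_size
  xs <- lapply(frames, resize_nn, S, S)
  ys <- lapply(masks, function(m) (resize_nn(m, S, S) > 0) * 1)

  with_seed(config$seed, {
    n <- length(xs)
    sp <- split_indices(n, config$split)
    tr <- sp$train; va <- sp$val
    if (length(tr) == 0) tr <- seq_len(n)
    if (length(va) == 0) va <- tr
    weights <- unet_init_weights(config$base_width)
    vel <- lapply(weights, function(w) w * 0)
    best <- list(dsc = -Inf, weights = weights, epoch = 0L)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_dsc = numeric(0))
    stall <- 0L
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr * config$lr_gamma^((ep - 1) %/% config$lr_step)
      ord <- sample(tr)
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        xb <- array(0, c(S, S, length(idx)))
        yb <- array(0, c(S, S, length(idx)))
        for (j in seq_along(idx)) {
          xi <- xs[[idx[j]]]; yi <- ys[[idx[j]]]
          if (config$augment) {
            if (runif(1) < 0.5) { xi <- xi[, rev(seq_len(S))]
                                  yi <- yi[, rev(seq_len(S))] }
            if (runif(1) < 0.5) { xi <- xi[rev(seq_len(S)), ]
                                  yi <- yi[rev(seq_len(S)), ] }
          }
          xb[, , j] <- xi; yb[, , j] <- yi
        }
        res <- unet_grad(weights, xb, yb)
        for (l in seq_along(weights)) {
          vel[[l]] <- config$momentum * vel[[l]] - lr * res$grads[[l]]
          weights[[l]] <- weights[[l]] + vel[[l]]
        }
        losses <- c(losses, res$loss)
      }
      val_dsc <- mean(vapply(va, function(i) {
        p <- unet_infer(weights, xs[[i]])
        hard_dice((p >= config$threshold) * 1, ys[[i]])
      }, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = mean(losses),
                                     val_dsc = val_dsc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", ep,
                        mean(losses), val_dsc))
      if (val_dsc > best$dsc) {
        best <- list(dsc = val_dsc, weights = weights, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    structure(list(weights = best$weights, best_val_dsc = best$dsc,
                   best_epoch = best$epoch, config = config, split = sp,
                   history = hist),
              class = "blink_unet")
  })
}

#' @export
print.blink_unet <- function(x, ...) {
  cat(sprintf("U-Net eyelid segmenter: base width %d, input %dx%d\n",
              x$config$base_width, x$config$input_size, x$config$input_size))
  cat(sprintf("  trained %d epochs; best validation DSC %.4f (epoch %d)\n",
              nrow(x$history), x$best_val_dsc, x$best_epoch))
  invisible(x)
}

#' Segment one frame
#'
#' Resizes the grayscale frame to the network's input size
#' (nearest-neighbour), runs the network, thresholds the probability map,
#' and resizes the binary mask back to the original frame resolution by
#' nearest-neighbour so the IPH is computed in original image coordinates.
#'
#' @param model A `"blink_unet"` from [train_segmentation()].
#' @param image Grayscale matrix in `[0, 1]`.
#' @return Binary mask matrix with the same shape as `image`.
#' @export
segment_frame <- function(model, image) {
  if (!inherits(model, "blink_unet") || is.null(model$weights))
    stopf("model is not a trained segmentation network")
  S <- model$config$input_size
  p <- unet_infer(model$weights, resize_nn(image, S, S))
  resize_nn((p >= model$config$threshold) * 1, nrow(image), ncol(image))
}

#' @export
predict.blink_unet <- function(object, newdata, ...) {
  if (is.matrix(newdata)) return(segment_frame(object, newdata))
  lapply(newdata, segment_frame, model = object)
}

#' Interpalpebral height of one mask
#'
#' The IPH of a frame is the maximum over columns of the vertical extent of
#' the mask's foreground in that column, `last_row - first_row + 1`
#' (0 for an empty mask), measured in original image pixels; `iph_frac`
#' normalizes by the image height.
#'
#' @param mask Binary matrix (any nonzero value is foreground).
#' @param image_h Image height in pixels used for normalization; defaults to
#'   `nrow(mask)`.
#' @return List with `iph_px` (pixels) and `iph_frac` (fraction of height).
#' @examples
#' m <- matrix(0, 600, 4); m[100:219, 2] <- 1
#' compute_iph(m)            # 120 px, 0.20
#' @export
compute_iph <- function(mask, image_h = nrow(mask)) {
  if (image_h <= 0) stopf("image_h must be positive")
  px <- iph_px_cpp(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  list(iph_px = px, iph_frac = px / image_h)
}

hard_dice <- function(pred, truth) {
  p <- sum(pred); g <- sum(truth)
  if (p + g == 0) return(1)         # agreement on absence
  2 * sum(pred * truth) / (p + g)
}

#' Segmentation overlap metrics
#'
#' Per-frame Dice similarity coefficient (DSC), intersection-over-union
#' (IOU), sensitivity (SEN) and balanced accuracy (BAC) between predicted
#' and reference masks, reported as mean and sd over frames. A frame where
#' both masks are empty scores 1 on all metrics (perfect agreement on
#' absence); ratios with empty denominators (e.g. sensitivity with no
#' foreground truth) are likewise taken as 1.
#'
#' @param pred,truth Equal-length lists of shape-matched binary masks.
#' @return List of class `"seg_metrics"`: `per_frame` data frame plus
#'   `mean` and `sd` named vectors over `dsc`, `iou`, `bac`, `sen`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("mask lists differ in length")
  if (length(pred) == 0) stopf("no masks to evaluate")
  rows <- lapply(seq_along(pred), function(i) {
    p <- (pred[[i]] > 0); g <- (truth[[i]] > 0)
    if (!identical(dim(p), dim(g))) stopf("mask shape mismatch at frame %d", i)
    tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
    dsc <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
    sen <- if (tp + fn == 0) 1 else tp / (tp + fn)
    spc <- if (tn + fp == 0) 1 else tn / (tn + fp)
    data.frame(dsc = dsc, iou = iou, bac = (sen + spc) / 2, sen = sen)
  })
  per <- do.call(rbind, rows)
  structure(list(per_frame = per, mean = colMeans(per),
                 sd = apply(per, 2, sd)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat("Segmentation metrics (mean ± sd over frames):\n")
  for (m in names(x$mean))
    cat(sprintf("  %s: %.4f ± %.4f\n", toupper(m), x$mean[[m]],
                if (is.na(x$sd[[m]])) 0 else x$sd[[m]]))
  invisible(x)
}
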