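# Training loop: per-image forward/backward with gradient accumulation
# over mini-batches and Adam updates. Images are processed one at a time
# (the loss is a sum over images, so batch gradients are exact sums).

#' Training configuration
#'
#' The reference protocol trains 100 epochs with Adam, learning rate
#' 0.001, batch size 16; the desk-scale default shipped here (8 epochs,
#' batch 8) keeps five-fold training tractable on one CPU. All fields are
#' overridable.
#'
#' @param epochs Number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size Images per optimizer step.
#' @param weights A [loss_weights()].
#' @param box_mode `"sse"` or `"ciou"` box regression.
#' @param warmup Fraction of total steps with linearly ramped learning
#'   rate; the remainder follows cosine decay to `final_lr_frac * lr`.
#'   `warmup = 0, final_lr_frac = 1` gives a constant rate.
#' @param final_lr_frac End-of-schedule learning-rate fraction.
#' @param seed Shuffling seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 8L, lr = 0.001, batch_size = 8L,
                         weights = loss_weights(), box_mode = "sse",
                         warmup = 0.1, final_lr_frac = 0.1, seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1, warmup >= 0, warmup < 1,
            final_lr_frac > 0, final_lr_frac <= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), weights = weights,
                 box_mode = box_mode, warmup = warmup,
                 final_lr_frac = final_lr_frac, seed = as.integer(seed)),
            class = "train_config")
}

# Learning rate at step t of n: linear warmup then cosine decay.
lr_at <- function(cfg, t, n) {
  wsteps <- max(1, floor(cfg$warmup * n))
  if (t <= wsteps && cfg$warmup > 0) return(cfg$lr * t / wsteps)
  frac <- (t - wsteps) / max(1, n - wsteps)
  lo <- cfg$lr * cfg$final_lr_frac
  lo + (cfg$lr - lo) * (1 + cos(pi * frac)) / 2
}

adam_state_new <- function() new.env(parent = emptyenv())

adam_update <- function(model, G, state, lr, scale = 1,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (state$t %||% 0L) + 1L
  t <- state$t
  for (nm in ls(G)) {
    g <- G[[nm]] * scale
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    layer <- parts[1]; field <- parts[2]
    m <- state[[paste0(nm, ".m")]] %||% (g * 0)
    v <- state[[paste0(nm, ".v")]] %||% (g * 0)
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[paste0(nm, ".m")]] <- m
    state[[paste0(nm, ".v")]] <- v
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    model$params[[layer]][[field]] <-
      model$params[[layer]][[field]] - lr * mh / (sqrt(vh) + eps)
  }
  model
}

#' Train a detector
#'
#' @param model A `detector_model` from [build_detector()].
#' @param index A `dataset_index` whose images match the model's input
#'   size.
#' @param cfg A [train_config()].
#' @param val_rows Optional row indices of `index$files` used as a
#'   held-out validation set; when given, validation mAP@.5 is logged per
#'   epoch.
#' @param train_rows Row indices to train on (default: all but
#'   `val_rows`).
#' @param verbose Print per-epoch progress.
#' @return The trained model, with the per-epoch log (`l_obj`, `l_cls`,
#'   `l_conf`, `total`, `val_map50`) attached as `model$train_log`.
#' @export
train_detector <- function(model, index, cfg = train_config(),
                           val_rows = integer(), train_rows = NULL,
                           verbose = FALSE) {
  if (is.null(train_rows)) train_rows <- setdiff(seq_len(nrow(index$files)),
                                                 val_rows)
  stopifnot(length(train_rows) >= 1)
  dcfg <- model$config
  cache_bytes <- length(train_rows) * prod(dcfg$input_size) * 3 * 8
  use_cache <- cache_bytes < 4e8
  cache <- if (use_cache) lapply(train_rows, function(i) load_annotated(index, i))
  # target assignment depends only on the labels: compute it once per image
  asg_cache <- lapply(seq_along(train_rows), function(ii) {
    img <- if (use_cache) cache[[ii]] else load_annotated(index, train_rows[ii])
    assign_targets(img$boxes, dcfg)
  })
  state <- adam_state_new()
  log_rows <- list()
  steps_per_epoch <- ceiling(length(train_rows) / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + epoch, sample(seq_along(train_rows)))
    comp <- c(l_obj = 0, l_cls = 0, l_conf = 0, total = 0)
    nb <- 0L
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idxs <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      G <- new.env(parent = emptyenv())
      for (ii in idxs) {
        img <- if (use_cache) cache[[ii]] else load_annotated(index, train_rows[ii])
        fwd <- detector_forward(model, img$pixels, train = TRUE)
        asg <- asg_cache[[ii]]
        ls <- detection_loss(fwd$preds, asg, cfg$weights,
                             box_mode = cfg$box_mode, with_grad = TRUE)
        detector_backward(fwd, ls$grads, G)
        comp <- comp + c(ls$l_obj, ls$l_cls, ls$l_conf, ls$total)
      }
      step <- step + 1L
      model <- adam_update(model, G, state, lr_at(cfg, step, total_steps),
                           scale = 1 / length(idxs))
      nb <- nb + 1L
    }
    row <- as.list(comp / length(ord))
    names(row) <- c("l_obj", "l_cls", "l_conf", "total")
    row$epoch <- epoch
    row$val_map50 <- NA_real_
    if (length(val_rows)) {
      ev <- evaluate_model(model, index, val_rows, score_thresh = 0.05)
      row$val_map50 <- ev$map50
    }
    log_rows[[epoch]] <- as.data.frame(row)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f%s", epoch, row$total,
                      if (!is.na(row$val_map50))
                        sprintf(", val mAP@.5 %.3f", row$val_map50) else ""))
    }
    if (!is.finite(row$total)) {
      stop("training diverged (non-finite loss) at epoch ", epoch)
    }
  }
  model$train_log <- do.call(rbind, log_rows)
  model
}

#' Run a trained detector over dataset rows
#'
#' Forward pass, decode, class-wise NMS per image.
#'
#' @param model A trained `detector_model`.
#' @param index A `dataset_index`.
#' @param rows Row indices of `index$files` to predict on.
#' @param score_thresh Decode threshold.
#' @param nms_iou NMS threshold.
#' @return A detection `data.frame` across the images.
#' @export
predict_dataset <- function(model, index, rows = seq_len(nrow(index$files)),
                            score_thresh = 0.25, nms_iou = 0.45) {
  out <- lapply(rows, function(i) {
    img <- load_annotated(index, i)
    fwd <- detector_forward(model, img$pixels)
    d <- decode_predictions(fwd$preds, model$config, score_thresh,
                            image_id = img$image_id)
    nms(d, nms_iou)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) empty_detections() else res
}

#' Collect ground-truth boxes of dataset rows as a flat table
#'
#' @param index A `dataset_index`.
#' @param rows Row indices of `index$files`.
#' @return A `data.frame` with `image_id`, `class_id`, `cx`, `cy`, `w`,
#'   `h` — the ground-truth format consumed by [map_suite()].
#' @export
index_ground_truth <- function(index, rows = seq_len(nrow(index$files))) {
  out <- lapply(rows, function(i) {
    b <- read_yolo_labels(index$files$label[i])
    if (nrow(b) == 0L) return(NULL)
    cbind(data.frame(image_id = index$files$image_id[i]), b)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    data.frame(image_id = character(), class_id = integer(), cx = numeric(),
               cy = numeric(), w = numeric(), h = numeric())
  } else res
}

# Predict + evaluate rows of an index in one go.
evaluate_model <- function(model, index, rows, score_thresh = 0.05,
                           nms_iou = 0.45, op_thresh = 0.25) {
  dets <- predict_dataset(model, index, rows, score_thresh, nms_iou)
  gts <- index_ground_truth(index, rows)
  map_suite(dets, gts, score_thresh = op_thresh,
            total_cells = length(rows) * total_anchor_cells(model$config))
}
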