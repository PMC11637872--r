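# The detector: a compact single-stage, three-scale anchor network.
# Backbone: strided 3x3 conv stages with residual refinement blocks and
# squeeze-excitation attention after the shallow stages; an SPPF block
# (stacked stride-1 max-pools + 1x1 fuse) at the deepest stage. Neck:
# top-down (FPN) then bottom-up (PAN) fusion by channel concatenation and
# 3x3 convs; efficient channel attention on each of the three fused
# outputs. Heads: 1x1 convs emitting, per grid cell and per anchor,
# (t_x, t_y, t_w, t_h, t_conf, class logits) at strides 8, 16 and 32.

#' Detector configuration
#'
#' @param n_classes Number of object classes.
#' @param input_size `(H, W)`, both divisible by 32.
#' @param widths Channel widths of the five backbone stages (strides
#'   2, 4, 8, 16, 32).
#' @param anchors List of three `3 x 2` matrices of anchor `(w, h)` pixel
#'   sizes for the stride-8, 16 and 32 scales. Default: anchors scaled to
#'   the input size, small at stride 8 through large at stride 32; see
#'   [kmeans_anchors()] to fit them to a dataset.
#' @param use_se Apply squeeze-excitation after the shallow backbone
#'   stages (strides 4 and 8).
#' @param use_eca Apply efficient channel attention to the three neck
#'   outputs.
#' @param seed Parameter-initialization seed.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(n_classes, input_size = c(320L, 320L),
                            widths = c(8L, 16L, 32L, 48L, 64L),
                            anchors = NULL, use_se = TRUE, use_eca = TRUE,
                            seed = 1L) {
  if (any(input_size %% 32 != 0) || any(input_size < 32)) {
    stop("configuration error: input_size must be divisible by 32")
  }
  stopifnot(n_classes >= 1, length(widths) == 5L, all(widths >= 2))
  if (is.null(anchors)) {
    m <- min(input_size)
    frac <- list(rbind(c(.09, .09), c(.14, .09), c(.09, .14)),
                 rbind(c(.20, .20), c(.30, .19), c(.19, .30)),
                 rbind(c(.42, .42), c(.58, .36), c(.36, .58)))
    anchors <- lapply(frac, function(f) f * m)
  }
  stopifnot(length(anchors) == 3L,
            all(vapply(anchors, function(a) all(dim(a) == c(3L, 2L)), logical(1))),
            all(unlist(anchors) > 0))
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 widths = as.integer(widths), anchors = anchors,
                 n_anchors = 3L, strides = c(8L, 16L, 32L),
                 use_se = isTRUE(use_se), use_eca = isTRUE(use_eca),
                 seed = as.integer(seed)),
            class = "detector_config")
}

#' Fit anchors to a dataset by k-means
#'
#' Clusters the pixel dimensions of all ground-truth boxes into 9 anchor
#' shapes and assigns them, sorted by area, to the three scales (smallest
#' three to stride 8, largest three to stride 32).
#'
#' @param index A `dataset_index`.
#' @param input_size Target input size `(H, W)` in pixels.
#' @param seed RNG seed for k-means.
#' @return A list of three `3 x 2` anchor matrices.
#' @export
kmeans_anchors <- function(index, input_size = c(320L, 320L), seed = 1L) {
  gt <- do.call(rbind, lapply(index$files$label, read_yolo_labels))
  wh <- cbind(gt$w * input_size[2], gt$h * input_size[1])
  if (nrow(wh) < 9L) wh <- wh[rep(seq_len(nrow(wh)), length.out = 9L), ]
  km <- with_seed(seed, kmeans(wh, centers = 9L, nstart = 5L, iter.max = 50L))
  cent <- km$centers[order(km$centers[, 1] * km$centers[, 2]), , drop = FALSE]
  lapply(1:3, function(s) unname(cent[(s - 1L) * 3L + 1:3, , drop = FALSE]))
}

conv_param <- function(cin, cout, k, stride, pad, gain = 1) {
  fan_in <- k * k * cin
  lim <- gain * sqrt(6 / fan_in)
  list(W = matrix(runif(k * k * cin * cout, -lim, lim), k * k * cin, cout),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
}

#' Build a detector model
#'
#' Instantiates all parameters (seeded, so two builds with the same config
#' are identical) for the backbone, neck, attention blocks and the three
#' prediction heads. Head confidence biases start strongly negative so the
#' untrained model predicts near-zero objectness everywhere.
#'
#' @param config A [detector_config()].
#' @return An object of class `detector_model` with elements `config` and
#'   `params`.
#' @export
build_detector <- function(config) {
  stopifnot(inherits(config, "detector_config"))
  w <- config$widths
  nc <- config$n_classes
  no <- config$n_anchors * (5L + nc)
  with_seed(config$seed, {
    p <- list(
      b0 = conv_param(3L, w[1], 3L, 2L, 1L),
      b1 = conv_param(w[1], w[2], 3L, 2L, 1L),
      r1 = conv_param(w[2], w[2], 3L, 1L, 1L),
      b2 = conv_param(w[2], w[3], 3L, 2L, 1L),
      r2 = conv_param(w[3], w[3], 3L, 1L, 1L),
      b3 = conv_param(w[3], w[4], 3L, 2L, 1L),
      r3 = conv_param(w[4], w[4], 3L, 1L, 1L),
      b4 = conv_param(w[4], w[5], 3L, 2L, 1L),
      r4 = conv_param(w[5], w[5], 3L, 1L, 1L),
      sppf = conv_param(4L * w[5], w[5], 1L, 1L, 0L),
      lat5 = conv_param(w[5], w[4], 1L, 1L, 0L),
      fpn4 = conv_param(2L * w[4], w[4], 3L, 1L, 1L),
      lat4 = conv_param(w[4], w[3], 1L, 1L, 0L),
      fpn3 = conv_param(2L * w[3], w[3], 3L, 1L, 1L),
      down3 = conv_param(w[3], w[3], 3L, 2L, 1L),
      pan4 = conv_param(2L * w[3], w[4], 3L, 1L, 1L),
      down4 = conv_param(w[4], w[4], 3L, 2L, 1L),
      pan5 = conv_param(2L * w[4], w[5], 3L, 1L, 1L),
      head3 = conv_param(w[3], no, 1L, 1L, 0L),
      head4 = conv_param(w[4], no, 1L, 1L, 0L),
      head5 = conv_param(w[5], no, 1L, 1L, 0L)
    )
    if (config$use_se) {
      se1 <- se_params(w[2], seed = config$seed + 101L)
      se2 <- se_params(w[3], seed = config$seed + 102L)
      p$se1 <- list(W1 = se1$W1, W2 = se1$W2)
      p$se2 <- list(W1 = se2$W1, W2 = se2$W2)
    }
    if (config$use_eca) {
      p$eca3 <- list(kernel = eca_params(w[3], seed = config$seed + 201L))
      p$eca4 <- list(kernel = eca_params(w[4], seed = config$seed + 202L))
      p$eca5 <- list(kernel = eca_params(w[5], seed = config$seed + 203L))
    }
    # the confidence channel is linear with a zero target on empty cells;
    # zero bias starts the untrained model at near-zero objectness
    structure(list(config = config, params = p), class = "detector_model")
  })
}

#' Number of trainable parameters
#'
#' @param model A `detector_model`.
#' @return Integer parameter count (a pure function of the config).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) {
    sum(vapply(p[names(p) %in% c("W", "b", "W1", "W2", "kernel")], length,
               integer(1)))
  }, integer(1)))
}

#' Detector forward pass
#'
#' Runs one image through backbone, neck, attention and heads, returning
#' the three raw prediction grids (`S x S x (3 * (5 + n_classes))` at
#' strides 8, 16, 32). With `train = TRUE` the computation tape is kept so
#' [detector_backward()] can backpropagate through it.
#'
#' @param model A `detector_model`.
#' @param pixels `H x W x 3` array matching the config input size.
#' @param train Keep the tape for backprop.
#' @param bypass_attention Force all attention gates to the identity
#'   (ablation switch; gating is purely multiplicative).
#' @return List with `preds` (named `p3`, `p4`, `p5`) and, in training
#'   mode, `tape` and `head_ids`.
#' @export
detector_forward <- function(model, pixels, train = FALSE,
                             bypass_attention = FALSE) {
  cfg <- model$config
  d <- dim(pixels)
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2] || d[3] != 3L) {
    stop("shape error: expected ", cfg$input_size[1], "x", cfg$input_size[2],
         "x3 input, got ", paste(d, collapse = "x"))
  }
  p <- model$params
  tape <- tape_new()
  x <- tape_push(tape, pixels)
  use_se <- cfg$use_se && !bypass_attention
  use_eca <- cfg$use_eca && !bypass_attention

  h <- op_conv(tape, x, p, "b0")
  h <- op_conv(tape, h, p, "b1")
  h <- op_add(tape, op_conv(tape, h, p, "r1"), h)
  if (use_se) h <- op_se(tape, h, p, "se1")
  h <- op_conv(tape, h, p, "b2")
  h <- op_add(tape, op_conv(tape, h, p, "r2"), h)
  if (use_se) h <- op_se(tape, h, p, "se2")
  B3 <- h
  h <- op_conv(tape, h, p, "b3")
  B4 <- op_add(tape, op_conv(tape, h, p, "r3"), h)
  h <- op_conv(tape, B4, p, "b4")
  h <- op_add(tape, op_conv(tape, h, p, "r4"), h)
  m1 <- op_maxpool(tape, h)
  m2 <- op_maxpool(tape, m1)
  m3 <- op_maxpool(tape, m2)
  B5 <- op_conv(tape, op_concat(tape, c(h, m1, m2, m3)), p, "sppf")

  T5 <- op_conv(tape, B5, p, "lat5")
  F4 <- op_conv(tape, op_concat(tape, c(op_upsample2(tape, T5), B4)), p, "fpn4")
  T4 <- op_conv(tape, F4, p, "lat4")
  N3 <- op_conv(tape, op_concat(tape, c(op_upsample2(tape, T4), B3)), p, "fpn3")
  D3 <- op_conv(tape, N3, p, "down3")
  N4 <- op_conv(tape, op_concat(tape, c(D3, T4)), p, "pan4")
  D4 <- op_conv(tape, N4, p, "down4")
  N5 <- op_conv(tape, op_concat(tape, c(D4, T5)), p, "pan5")

  E3 <- if (use_eca) op_eca(tape, N3, p, "eca3") else N3
  E4 <- if (use_eca) op_eca(tape, N4, p, "eca4") else N4
  E5 <- if (use_eca) op_eca(tape, N5, p, "eca5") else N5

  H3 <- op_conv(tape, E3, p, "head3", act = FALSE)
  H4 <- op_conv(tape, E4, p, "head4", act = FALSE)
  H5 <- op_conv(tape, E5, p, "head5", act = FALSE)

  preds <- list(p3 = tape_value(tape, H3), p4 = tape_value(tape, H4),
                p5 = tape_value(tape, H5))
  if (!train) return(list(preds = preds))
  list(preds = preds, tape = tape, head_ids = c(H3, H4, H5))
}

#' Backpropagate head gradients through the detector
#'
#' Accumulates parameter gradients into environment `G` (keyed
#' `"layer.field"`), given the gradient of the loss with respect to each
#' head grid (e.g. from [detection_loss()] with `with_grad = TRUE`).
#'
#' @param fwd Result of [detector_forward()] with `train = TRUE`.
#' @param dpreds List of gradients (`p3`, `p4`, `p5`).
#' @param G Environment receiving accumulated gradients.
#' @return `NULL`, invisibly.
#' @export
detector_backward <- function(fwd, dpreds, G) {
  seeds <- list(dpreds$p3, dpreds$p4, dpreds$p5)
  names(seeds) <- as.character(fwd$head_ids)
  tape_backward(fwd$tape, seeds, G)
}
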