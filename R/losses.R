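# Target assignment and the three-part grid loss: squared-error box
# regression over responsible anchor-cells (as printed -- no square roots;
# a CIoU box mode is available as a config switch), squared-error class
# probabilities, and squared-error confidence with IoU-valued targets on
# responsible cells and a down-weighted zero target elsewhere.

#' Loss weights
#'
#' `total = box * l_obj + cls * l_cls + conf * l_conf`; `noobj` scales the
#' confidence loss of anchor-cells not responsible for any object.
#'
#' @param box,cls,conf Component weights (defaults 0.05, 0.5, 1).
#' @param noobj No-object confidence down-weight (default 0.5).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(box = 0.05, cls = 0.5, conf = 1, noobj = 0.5) {
  stopifnot(box >= 0, cls >= 0, conf >= 0, noobj >= 0)
  structure(list(box = box, cls = cls, conf = conf, noobj = noobj),
            class = "loss_weights")
}

#' Assign ground-truth boxes to anchor-cells
#'
#' Each ground-truth box is assigned to the grid cell containing its
#' center, at every scale where an anchor matches the box shape
#' (`max(w/wa, wa/w, h/ha, ha/h) < 4`). A box matched by no anchor falls
#' back to the single best-ratio anchor, so every box has at least one
#' responsible anchor-cell. Grid rows/cols are 0-based.
#'
#' @param boxes A box `data.frame` (normalized center format).
#' @param config A [detector_config()].
#' @return An object of class `assignment` with a `cells` data.frame
#'   (`scale`, `anchor`, `row`, `col`, `gt`, `class_id`) and the `boxes`.
#' @export
assign_targets <- function(boxes, config) {
  validate_boxes(boxes, config$n_classes)
  H <- config$input_size[1]; W <- config$input_size[2]
  rows <- list()
  occupied <- character()
  if (nrow(boxes)) {
    for (g in seq_len(nrow(boxes))) {
      bw_px <- boxes$w[g] * W; bh_px <- boxes$h[g] * H
      cand <- do.call(rbind, lapply(1:3, function(s) {
        a <- config$anchors[[s]]
        ratio <- pmax(bw_px / a[, 1], a[, 1] / bw_px,
                      bh_px / a[, 2], a[, 2] / bh_px)
        data.frame(scale = s, anchor = 1:3, ratio = ratio)
      }))
      sel <- cand[cand$ratio < 4, , drop = FALSE]
      if (nrow(sel) == 0L) sel <- cand[which.min(cand$ratio), , drop = FALSE]
      for (j in seq_len(nrow(sel))) {
        s <- sel$scale[j]
        S_r <- H %/% config$strides[s]; S_c <- W %/% config$strides[s]
        row0 <- min(floor(boxes$cy[g] * S_r), S_r - 1L)
        col0 <- min(floor(boxes$cx[g] * S_c), S_c - 1L)
        key <- paste(s, sel$anchor[j], row0, col0)
        if (key %in% occupied) next
        occupied <- c(occupied, key)
        rows[[length(rows) + 1L]] <- data.frame(
          scale = s, anchor = sel$anchor[j], row = row0, col = col0,
          gt = g, class_id = boxes$class_id[g])
      }
    }
  }
  cells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scale = integer(), anchor = integer(), row = integer(),
               col = integer(), gt = integer(), class_id = integer())
  structure(list(cells = cells, boxes = boxes, config = config),
            class = "assignment")
}

# Decode one anchor-cell's raw channels into a normalized box + conf +
# class probabilities. Shared by the loss and the prediction decoder.
# Offsets and extents go through sigmoids (cell-relative position,
# anchor-scaled (2*sigmoid)^2 extent); the confidence channel is LINEAR --
# the squared-error confidence loss regresses the raw output against the
# IoU target directly, which avoids sigmoid saturation on rare positives
# (inference clamps it to [0, 1]).
decode_cell <- function(t, anchor_wh, row0, col0, S_r, S_c, input_size) {
  sx <- sigmoid(t[1]); sy <- sigmoid(t[2])
  sw <- sigmoid(t[3]); sh <- sigmoid(t[4])
  list(cx = (col0 + sx) / S_c, cy = (row0 + sy) / S_r,
       w = (2 * sw)^2 * anchor_wh[1] / input_size[2],
       h = (2 * sh)^2 * anchor_wh[2] / input_size[1],
       conf = t[5], probs = sigmoid(t[-(1:5)]),
       sx = sx, sy = sy, sw = sw, sh = sh)
}

#' Detection loss
#'
#' Computes the loss breakdown for one image's prediction grids under an
#' [assign_targets()] assignment:
#' * `l_obj` -- box term: sum over responsible anchor-cells of
#'   `(x - x_hat)^2 + (y - y_hat)^2 + (w - w_hat)^2 + (h - h_hat)^2` on
#'   normalized coordinates (`box_mode = "sse"`), or `1 - CIoU`
#'   (`box_mode = "ciou"`);
#' * `l_cls` -- sum over responsible cells and classes of squared
#'   probability error against the one-hot label;
#' * `l_conf` -- squared confidence error with target `IoU(pred, gt)` on
#'   responsible cells plus `noobj` times squared confidence on all other
#'   anchor-cells;
#' * `total = box * l_obj + cls * l_cls + conf * l_conf`.
#'
#' @param preds List of three raw grids (`p3`, `p4`, `p5`), each
#'   `S x S x (3 * (5 + n_classes))`, or decoded grids when
#'   `decoded = TRUE` (channels then hold `x, y, w, h, conf, probs`
#'   directly).
#' @param assignment From [assign_targets()].
#' @param weights A [loss_weights()].
#' @param decoded Treat the grids as already decoded (used for direct
#'   numeric checks).
#' @param box_mode `"sse"` (squared errors, as defined above) or `"ciou"`.
#' @param with_grad Also return `grads`, the analytic gradient of `total`
#'   with respect to each raw grid entry (raw mode only). The IoU-valued
#'   confidence target is treated as a constant (it is not differentiated
#'   through), the usual convention for moving targets.
#' @param conf_targets Optional numeric vector of fixed confidence
#'   targets, one per row of `assignment$cells`, replacing the live
#'   `IoU(pred, gt)` target (used to freeze the loss surface, e.g. for
#'   finite-difference checks).
#' @return A list (`l_obj`, `l_cls`, `l_conf`, `total`, `conf_targets`
#'   (the targets actually used), and optionally `grads`).
#' @export
detection_loss <- function(preds, assignment, weights = loss_weights(),
                           decoded = FALSE, box_mode = c("sse", "ciou"),
                           with_grad = FALSE, conf_targets = NULL) {
  box_mode <- match.arg(box_mode)
  cfg <- assignment$config
  nc <- cfg$n_classes
  per <- 5L + nc
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  l_obj <- 0; l_cls <- 0; l_conf_obj <- 0; l_conf_noobj <- 0
  grads <- if (with_grad) lapply(preds, function(p) array(0, dim(p))) else NULL
  cells <- assignment$cells
  used_targets <- numeric(nrow(cells))
  boxes <- assignment$boxes
  for (s in 1:3) {
    P <- preds[[s]]
    if (any(!is.finite(P))) {
      bad <- which(!is.finite(P), arr.ind = TRUE)[1, ]
      stop("numerical error: non-finite prediction at scale ", s, " cell (",
           bad[1], ",", bad[2], ",", bad[3], ")")
    }
    S_r <- dim(P)[1]; S_c <- dim(P)[2]
    sc_cells <- cells[cells$scale == s, , drop = FALSE]
    # confidence channels (everything starts as noobj, obj handled below)
    conf_idx <- (seq_len(cfg$n_anchors) - 1L) * per + 5L
    conf_hat <- P[, , conf_idx, drop = FALSE]  # linear confidence channel
    obj_mask <- array(FALSE, dim(conf_hat))
    if (nrow(sc_cells)) {
      obj_mask[cbind(sc_cells$row + 1L, sc_cells$col + 1L, sc_cells$anchor)] <- TRUE
    }
    l_conf_noobj <- l_conf_noobj + sum(conf_hat[!obj_mask]^2)
    if (with_grad) {
      dC <- weights$conf * weights$noobj * 2 * conf_hat
      dC[obj_mask] <- 0
      grads[[s]][, , conf_idx] <- grads[[s]][, , conf_idx, drop = FALSE] + dC
    }
    if (nrow(sc_cells) == 0L) next
    cell_rows <- which(cells$scale == s)
    for (r in seq_len(nrow(sc_cells))) {
      ce <- sc_cells[r, ]
      base <- (ce$anchor - 1L) * per
      t <- P[ce$row + 1L, ce$col + 1L, base + seq_len(per)]
      gt <- boxes[ce$gt, ]
      if (decoded) {
        dec <- list(cx = t[1], cy = t[2], w = t[3], h = t[4], conf = t[5],
                    probs = t[-(1:5)])
      } else {
        dec <- decode_cell(t, cfg$anchors[[s]][ce$anchor, ], ce$row, ce$col,
                           S_r, S_c, cfg$input_size)
      }
      pb <- c(dec$cx - dec$w / 2, dec$cy - dec$h / 2,
              dec$cx + dec$w / 2, dec$cy + dec$h / 2)
      gb <- c(gt$cx - gt$w / 2, gt$cy - gt$h / 2,
              gt$cx + gt$w / 2, gt$cy + gt$h / 2)
      iou_t <- if (!is.null(conf_targets)) conf_targets[cell_rows[r]] else
        box_iou(pb, gb)
      used_targets[cell_rows[r]] <- iou_t
      if (box_mode == "sse") {
        l_box_cell <- (dec$cx - gt$cx)^2 + (dec$cy - gt$cy)^2 +
                      (dec$w - gt$w)^2 + (dec$h - gt$h)^2
        dbox <- 2 * c(dec$cx - gt$cx, dec$cy - gt$cy,
                      dec$w - gt$w, dec$h - gt$h)
      } else {
        l_box_cell <- 1 - box_ciou(pb, gb)
        # numeric gradient of 1 - CIoU in the decoded box parameters;
        # responsible cells are few so this is cheap and robust
        eps <- 1e-6
        dbox <- vapply(1:4, function(q) {
          d0 <- c(dec$cx, dec$cy, dec$w, dec$h)
          dp <- d0; dm <- d0
          dp[q] <- dp[q] + eps; dm[q] <- dm[q] - eps
          f <- function(v) {
            1 - box_ciou(c(v[1] - v[3] / 2, v[2] - v[4] / 2,
                           v[1] + v[3] / 2, v[2] + v[4] / 2), gb)
          }
          (f(dp) - f(dm)) / (2 * eps)
        }, numeric(1))
      }
      l_obj <- l_obj + l_box_cell
      onehot <- as.numeric(seq_len(nc) - 1L == gt$class_id)
      l_cls <- l_cls + sum((onehot - dec$probs)^2)
      l_conf_obj <- l_conf_obj + (iou_t - dec$conf)^2
      if (with_grad && !decoded) {
        dloc <- numeric(per)
        # box params through the decode transform
        dloc[1] <- weights$box * dbox[1] * dec$sx * (1 - dec$sx) / S_c
        dloc[2] <- weights$box * dbox[2] * dec$sy * (1 - dec$sy) / S_r
        aw <- cfg$anchors[[s]][ce$anchor, 1]; ah <- cfg$anchors[[s]][ce$anchor, 2]
        dloc[3] <- weights$box * dbox[3] *
          8 * dec$sw * dec$sw * (1 - dec$sw) * aw / W
        dloc[4] <- weights$box * dbox[4] *
          8 * dec$sh * dec$sh * (1 - dec$sh) * ah / H
        # confidence (linear channel; IoU target treated as constant)
        dloc[5] <- weights$conf * 2 * (dec$conf - iou_t)
        # classes
        dloc[-(1:5)] <- weights$cls * 2 * (dec$probs - onehot) *
          dec$probs * (1 - dec$probs)
        grads[[s]][ce$row + 1L, ce$col + 1L, base + seq_len(per)] <-
          grads[[s]][ce$row + 1L, ce$col + 1L, base + seq_len(per)] + dloc
      }
    }
  }
  l_conf <- l_conf_obj + weights$noobj * l_conf_noobj
  out <- list(l_obj = l_obj, l_cls = l_cls, l_conf = l_conf,
              total = weights$box * l_obj + weights$cls * l_cls +
                      weights$conf * l_conf,
              conf_targets = used_targets)
  if (with_grad) out$grads <- grads
  out
}
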