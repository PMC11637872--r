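# Decoding raw grids into detections, non-maximum suppression, and the
# evaluation suite: per-class precision/recall/AP, mAP at IoU 0.5 and
# averaged over 0.50:0.05:0.95, Matthews correlation and ROC/AUC. The MCC
# and ROC need a true-negative count, which is undefined for pure
# detection; here TN is the number of anchor-cells (the model's finite
# decision space) that are neither responsible for a ground-truth box nor
# the source of an above-threshold detection.

#' Decode prediction grids into detections
#'
#' Applies the decode transform per anchor-cell: sigmoid offsets inside
#' the cell, anchor-scaled extents, `score = sigmoid(t_conf) * max class
#' probability` (the objectness-times-accuracy confidence), keeping the
#' arg-max class. Detections below `score_thresh` are dropped.
#'
#' @param preds List of three raw grids from the detector forward pass.
#' @param config A [detector_config()].
#' @param score_thresh Minimum score.
#' @param image_id Id attached to the detections.
#' @return A `data.frame` with columns `image_id`, `class_id`, `score`,
#'   `cx`, `cy`, `w`, `h`.
#' @export
decode_predictions <- function(preds, config, score_thresh = 0.25,
                               image_id = "img") {
  nc <- config$n_classes
  per <- 5L + nc
  out <- list()
  for (s in 1:3) {
    P <- preds[[s]]
    S_r <- dim(P)[1]; S_c <- dim(P)[2]
    col0 <- matrix(rep(0:(S_c - 1L), each = S_r), S_r, S_c)
    row0 <- matrix(rep(0:(S_r - 1L), S_c), S_r, S_c)
    for (a in seq_len(config$n_anchors)) {
      base <- (a - 1L) * per
      sx <- sigmoid(P[, , base + 1L]); sy <- sigmoid(P[, , base + 2L])
      sw <- sigmoid(P[, , base + 3L]); sh <- sigmoid(P[, , base + 4L])
      conf <- clamp(P[, , base + 5L], 0, 1)  # linear confidence channel
      probs <- matrix(sigmoid(P[, , base + 5L + seq_len(nc)]), S_r * S_c, nc)
      best <- max.col(probs, ties.method = "first")
      pbest <- probs[cbind(seq_len(S_r * S_c), best)]
      score <- as.numeric(conf) * pbest
      keep <- which(score >= score_thresh)
      if (!length(keep)) next
      aw <- config$anchors[[s]][a, 1]; ah <- config$anchors[[s]][a, 2]
      out[[length(out) + 1L]] <- data.frame(
        image_id = image_id, class_id = best[keep] - 1L, score = score[keep],
        cx = ((as.numeric(col0) + as.numeric(sx))[keep]) / S_c,
        cy = ((as.numeric(row0) + as.numeric(sy))[keep]) / S_r,
        w = (2 * as.numeric(sw)[keep])^2 * aw / config$input_size[2],
        h = (2 * as.numeric(sh)[keep])^2 * ah / config$input_size[1])
    }
  }
  if (!length(out)) return(empty_detections())
  do.call(rbind, out)
}

empty_detections <- function() {
  data.frame(image_id = character(), class_id = integer(), score = numeric(),
             cx = numeric(), cy = numeric(), w = numeric(), h = numeric())
}

# Deterministic detection ordering: score desc, ties by box coordinates.
order_detections <- function(d) {
  order(-d$score, d$cx, d$cy, d$w, d$h, d$class_id)
}

#' Greedy class-wise non-maximum suppression
#'
#' Sorts detections by descending score (ties broken by box coordinates so
#' the result is independent of input order) and keeps a detection iff its
#' IoU with every previously kept detection of the same class (and image)
#' is below `iou_thresh`.
#'
#' @param dets Detection `data.frame` (see [decode_predictions()]).
#' @param iou_thresh Suppression threshold (default 0.45).
#' @return The surviving detections, ordered by score.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  if (nrow(dets) == 0L) return(dets)
  dets <- dets[order_detections(dets), , drop = FALSE]
  corners <- boxes_to_corners(dets)
  keep <- logical(nrow(dets))
  for (grp in split(seq_len(nrow(dets)),
                    paste(dets$image_id, dets$class_id))) {
    kept <- integer()
    for (i in grp) {
      if (length(kept) &&
          any(iou_one_vs_many(corners[i, ], corners[kept, , drop = FALSE]) >=
              iou_thresh)) next
      kept <- c(kept, i)
      keep[i] <- TRUE
    }
  }
  dets[keep, , drop = FALSE]
}

#' Match detections against ground truth
#'
#' Greedy highest-score-first matching: each detection may claim at most
#' one still-unmatched ground-truth box of the same class and image with
#' IoU at least `iou_thresh` (the highest-IoU one). Matched detections are
#' true positives, the rest false positives; unmatched ground truth are
#' false negatives.
#'
#' @param dets Detection `data.frame`.
#' @param gts Ground-truth `data.frame` (`image_id`, `class_id`, `cx`,
#'   `cy`, `w`, `h`).
#' @param iou_thresh Matching threshold (default 0.5).
#' @return An object of class `match_result`: per-class score-ordered TP
#'   flags plus aggregate `TP`, `FP`, `FN`.
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  per_class <- list()
  TP <- FP <- FN <- 0L
  dcorn <- if (nrow(dets)) boxes_to_corners(dets) else NULL
  gcorn <- if (nrow(gts)) boxes_to_corners(gts) else NULL
  for (cl in classes) {
    di <- which(dets$class_id == cl)
    di <- di[order_detections(dets[di, , drop = FALSE])]
    gi <- which(gts$class_id == cl)
    matched <- logical(length(gi))
    flags <- logical(length(di))
    for (k in seq_along(di)) {
      i <- di[k]
      cand <- which(!matched & gts$image_id[gi] == dets$image_id[i])
      if (length(cand)) {
        ious <- iou_one_vs_many(dcorn[i, ], gcorn[gi[cand], , drop = FALSE])
        best <- which.max(ious)
        if (ious[best] >= iou_thresh) {
          matched[cand[best]] <- TRUE
          flags[k] <- TRUE
        }
      }
    }
    per_class[[as.character(cl)]] <- list(class_id = cl, flags = flags,
                                          scores = dets$score[di],
                                          n_gt = length(gi))
    TP <- TP + sum(flags); FP <- FP + sum(!flags)
    FN <- FN + sum(!matched)
  }
  structure(list(per_class = per_class, TP = TP, FP = FP, FN = FN),
            class = "match_result")
}

#' Precision and recall of a match result
#'
#' `precision = TP / (TP + FP)` (0 when there are no detections) and
#' `recall = TP / (TP + FN)` (1 when there is no ground truth).
#'
#' @param m A `match_result` (or a list with `TP`, `FP`, `FN`).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
precision_recall <- function(m) {
  p <- if (m$TP + m$FP == 0) 0 else m$TP / (m$TP + m$FP)
  r <- if (m$TP + m$FN == 0) 1 else m$TP / (m$TP + m$FN)
  c(precision = p, recall = r)
}

#' Average precision from score-ordered TP flags
#'
#' `all_point`: area under the precision envelope,
#' `sum (r_i - r_(i-1)) * max_(r >= r_i) p(r)`. `coco101`: mean of the
#' envelope precision sampled at 101 recall points 0, 0.01, ..., 1.
#'
#' @param flags Logical TP flags in decreasing-score order.
#' @param n_gt Number of ground-truth boxes (0 gives `NA`: AP undefined,
#'   excluded from means).
#' @param mode `"all_point"` or `"coco101"`.
#' @return AP in `[0, 1]`, or `NA` when undefined.
#' @export
average_precision <- function(flags, n_gt, mode = c("all_point", "coco101")) {
  mode <- match.arg(mode)
  if (n_gt == 0L) return(NA_real_)
  if (!length(flags) || !any(flags)) return(0)
  tp <- cumsum(flags)
  prec <- tp / seq_along(flags)
  rec <- tp / n_gt
  env <- rev(cummax(rev(prec)))  # precision envelope: max over r' >= r
  if (mode == "all_point") {
    prev <- c(0, rec[-length(rec)])
    return(sum((rec - prev) * env))
  }
  q <- vapply(seq(0, 1, by = 0.01), function(r) {
    i <- which(rec >= r - 1e-9)  # guard exact-recall grid points
    if (length(i)) env[i[1]] else 0
  }, numeric(1))
  mean(q)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; defined as 0
#' when any denominator factor is 0.
#'
#' @param TP,TN,FP,FN Non-negative counts.
#' @return MCC in `[-1, 1]`.
#' @export
mcc_score <- function(TP, TN, FP, FN) {
  den <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den <= 0) return(0)
  (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den)
}

total_anchor_cells <- function(config) {
  sum(vapply(config$strides, function(s) {
    config$n_anchors * (config$input_size[1] %/% s) * (config$input_size[2] %/% s)
  }, numeric(1)))
}

#' ROC curve over score thresholds
#'
#' Sweeps thresholds (default 0.1 to 1.0 in steps of 0.1); at each, TPR =
#' TP/(TP+FN) and FPR = FP/(FP+TN) with the detection-adapted TN
#' `total_cells - (number of GT boxes + FP)`. AUC is the trapezoid over
#' the swept points plus the endpoints (0,0) and (1,1). A detector
#' producing no detections anywhere is flagged degenerate.
#'
#' @param dets,gts Detection and ground-truth data frames.
#' @param total_cells Number of anchor-cells in the model's decision
#'   space; see the package's `total_anchor_cells`-style accounting in the
#'   methods vignette.
#' @param thresholds Score thresholds to sweep.
#' @param iou_thresh Matching IoU.
#' @return List with `points` (threshold, TPR, FPR), `auc`, `degenerate`.
#' @export
roc_curve <- function(dets, gts, total_cells,
                      thresholds = seq(0.1, 1, by = 0.1), iou_thresh = 0.5) {
  pts <- do.call(rbind, lapply(thresholds, function(th) {
    d <- dets[dets$score >= th, , drop = FALSE]
    m <- match_detections(d, gts, iou_thresh)
    tn <- max(0, total_cells - (nrow(gts) + m$FP))
    data.frame(threshold = th,
               TPR = if (m$TP + m$FN == 0) 0 else m$TP / (m$TP + m$FN),
               FPR = if (m$FP + tn == 0) 0 else m$FP / (m$FP + tn))
  }))
  degenerate <- all(pts$TPR == 0)
  xs <- c(0, pts$FPR, 1); ys <- c(0, pts$TPR, 1)
  o <- order(xs, ys)
  xs <- xs[o]; ys <- ys[o]
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
  list(points = pts, auc = auc, degenerate = degenerate)
}

#' Full evaluation suite
#'
#' Per-class precision/recall (at `score_thresh`, IoU 0.5), per-class AP,
#' mAP@.5 (all-point interpolation), mAP@.5:.95 (101-point interpolation
#' averaged over IoU 0.50:0.05:0.95), micro-averaged precision/recall,
#' and -- when `total_cells` is supplied -- MCC and the ROC/AUC sweep.
#' Classes without ground truth are excluded from the mAP means.
#'
#' @param dets Detections (all scores; the suite thresholds internally).
#' @param gts Ground truth.
#' @param score_thresh Operating threshold for P/R/MCC.
#' @param total_cells Optional anchor-cell count enabling MCC and ROC.
#' @param ap_mode Interpolation for mAP@.5 and per-class AP.
#' @return An object of class `eval_report`.
#' @export
map_suite <- function(dets, gts, score_thresh = 0.25, total_cells = NULL,
                      ap_mode = "all_point") {
  m50 <- match_detections(dets, gts, 0.5)
  classes <- sort(unique(gts$class_id))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    pc <- m50$per_class[[as.character(cl)]]
    dth <- dets[dets$class_id == cl & dets$score >= score_thresh, , drop = FALSE]
    mth <- match_detections(dth, gts[gts$class_id == cl, , drop = FALSE], 0.5)
    pr <- precision_recall(mth)
    data.frame(class_id = cl, n_gt = pc$n_gt, precision = pr[["precision"]],
               recall = pr[["recall"]],
               ap50 = average_precision(pc$flags, pc$n_gt, ap_mode))
  }))
  map50 <- mean(per_class$ap50[per_class$n_gt > 0], na.rm = TRUE)
  iou_grid <- seq(0.5, 0.95, by = 0.05)
  ap_mat <- vapply(iou_grid, function(th) {
    m <- match_detections(dets, gts, th)
    vapply(classes, function(cl) {
      pc <- m$per_class[[as.character(cl)]]
      average_precision(pc$flags, pc$n_gt, "coco101")
    }, numeric(1))
  }, numeric(length(classes)))
  ap_mat <- matrix(ap_mat, nrow = length(classes))
  map5095 <- mean(ap_mat[per_class$n_gt > 0, , drop = FALSE], na.rm = TRUE)
  dth <- dets[dets$score >= score_thresh, , drop = FALSE]
  mth <- match_detections(dth, gts, 0.5)
  pr <- precision_recall(mth)
  out <- list(per_class = per_class, map50 = map50, map5095 = map5095,
              precision = pr[["precision"]], recall = pr[["recall"]],
              TP = mth$TP, FP = mth$FP, FN = mth$FN)
  if (!is.null(total_cells)) {
    tn <- max(0, total_cells - (nrow(gts) + mth$FP))
    out$TN <- tn
    out$mcc <- mcc_score(mth$TP, tn, mth$FP, mth$FN)
    roc <- roc_curve(dets, gts, total_cells)
    out$roc <- roc$points
    out$auc <- roc$auc
    out$roc_degenerate <- roc$degenerate
  }
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: mAP@.5 %.3f, mAP@.5:.95 %.3f, P %.3f, R %.3f%s>\n",
              x$map50, x$map5095, x$precision, x$recall,
              if (!is.null(x$mcc)) sprintf(", MCC %.3f", x$mcc) else ""))
  invisible(x)
}
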