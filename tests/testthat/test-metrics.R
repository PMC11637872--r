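test_that("decoding drops suppressed objectness and multiplies in class probability", {
  cfg <- detector_config(n_classes = 2L, input_size = c(64L, 64L),
                         widths = c(4L, 6L, 8L, 10L, 12L), seed = 1L)
  preds <- lapply(c(8L, 16L, 32L), function(s) {
    S <- 64L %/% s
    array(0, c(S, S, 21L))
  })
  names(preds) <- c("p3", "p4", "p5")
  # confidence 0 everywhere -> nothing survives any positive threshold
  expect_equal(nrow(decode_predictions(preds, cfg, 0.01)), 0L)
  # Pr(obj) = 1 with class probability 0.7 -> score 0.7
  preds$p3[3, 4, 5] <- 1
  preds$p3[3, 4, 6] <- qlogis(0.7)
  preds$p3[3, 4, 7] <- qlogis(0.1)
  d <- decode_predictions(preds, cfg, 0.5)
  expect_equal(nrow(d), 1L)
  expect_equal(d$score, 0.7, tolerance = 1e-9)
  expect_equal(d$class_id, 0L)
})

test_that("an encoded ground-truth box decodes back onto itself", {
  cfg <- detector_config(n_classes = 2L, input_size = c(64L, 64L),
                         widths = c(4L, 6L, 8L, 10L, 12L), seed = 1L)
  gt <- bbox(1L, 0.55, 0.4, 0.3, 0.25)
  asg <- assign_targets(gt, cfg)
  ce <- asg$cells[1, ]
  S <- 64L %/% cfg$strides[ce$scale]
  aw <- cfg$anchors[[ce$scale]][ce$anchor, 1]
  ah <- cfg$anchors[[ce$scale]][ce$anchor, 2]
  preds <- lapply(c(8L, 16L, 32L), function(s) {
    array(0, c(64L %/% s, 64L %/% s, 21L))
  })
  names(preds) <- c("p3", "p4", "p5")
  enc <- c(qlogis(gt$cx * S - ce$col), qlogis(gt$cy * S - ce$row),
           qlogis(sqrt(gt$w * 64 / aw) / 2), qlogis(sqrt(gt$h * 64 / ah) / 2),
           1, qlogis(0.01), qlogis(0.99))
  preds[[ce$scale]][ce$row + 1, ce$col + 1, (ce$anchor - 1) * 7 + 1:7] <- enc
  d <- decode_predictions(preds, cfg, 0.5)
  expect_equal(nrow(d), 1L)
  expect_equal(d$class_id, 1L)
  expect_gt(ref_iou(c(d$cx - d$w / 2, d$cy - d$h / 2, d$cx + d$w / 2,
                      d$cy + d$h / 2),
                    c(gt$cx - gt$w / 2, gt$cy - gt$h / 2, gt$cx + gt$w / 2,
                      gt$cy + gt$h / 2)), 0.99)
})

make_det <- function(cx, cy, w, h, score, class_id = 0L, image_id = "im1") {
  data.frame(image_id = image_id, class_id = class_id, score = score,
             cx = cx, cy = cy, w = w, h = h)
}

test_that("NMS keeps the strongest of duplicates and leaves disjoint boxes alone", {
  d <- rbind(make_det(0.5, 0.5, 0.2, 0.2, 0.9),
             make_det(0.5, 0.5, 0.2, 0.2, 0.8))
  expect_equal(nms(d, 0.45)$score, 0.9)
  d2 <- rbind(make_det(0.2, 0.2, 0.1, 0.1, 0.9),
              make_det(0.8, 0.8, 0.1, 0.1, 0.5))
  expect_equal(nrow(nms(d2, 0.45)), 2L)
  # different classes never suppress each other
  d3 <- rbind(make_det(0.5, 0.5, 0.2, 0.2, 0.9, 0L),
              make_det(0.5, 0.5, 0.2, 0.2, 0.8, 1L))
  expect_equal(nrow(nms(d3, 0.45)), 2L)
})

test_that("NMS equals the brute-force reference and ignores input order", {
  set.seed(31)
  for (trial in 1:5) {
    n <- 12
    d <- make_det(runif(n, 0.2, 0.8), runif(n, 0.2, 0.8), runif(n, 0.1, 0.4),
                  runif(n, 0.1, 0.4), runif(n), sample(0:1, n, TRUE))
    got <- nms(d, 0.45)
    want <- ref_nms(d, 0.45)
    expect_equal(got[order(-got$score), c("score", "cx", "cy")],
                 want[order(-want$score), c("score", "cx", "cy")],
                 ignore_attr = TRUE)
    shuf <- d[sample(n), ]
    got2 <- nms(shuf, 0.45)
    expect_equal(got2[order(-got2$score), ], got[order(-got$score), ],
                 ignore_attr = TRUE)
  }
})

test_that("matching is greedy by score with one ground truth per detection", {
  gt <- make_det(0.5, 0.5, 0.2, 0.2, 1)[, -3]
  # perfect detection
  m <- match_detections(make_det(0.5, 0.5, 0.2, 0.2, 1), gt, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
  # detection with no ground truth at all
  m2 <- match_detections(make_det(0.5, 0.5, 0.2, 0.2, 1), gt[0, ], 0.5)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 0L))
  # two detections on one box: the higher-scored one wins the match
  d <- rbind(make_det(0.5, 0.5, 0.2, 0.2, 0.9),
             make_det(0.51, 0.5, 0.2, 0.2, 0.8))
  m3 <- match_detections(d, gt, 0.5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1L, 1L, 0L))
  expect_true(m3$per_class[["0"]]$flags[1])
  expect_false(m3$per_class[["0"]]$flags[2])
  # count conservation: TP + FN = |GT|, TP + FP = |detections|
  fix <- make_eval_fixture(10, seed = 5)
  m4 <- match_detections(fix$dets, fix$gts, 0.5)
  expect_equal(m4$TP + m4$FN, nrow(fix$gts))
  expect_equal(m4$TP + m4$FP, nrow(fix$dets))
})

test_that("precision/recall follow the printed formulas and 0/0 conventions", {
  expect_equal(precision_recall(list(TP = 90, FP = 10, FN = 0))[["precision"]],
               0.9)
  expect_equal(precision_recall(list(TP = 90, FP = 0, FN = 15))[["recall"]],
               90 / 105)
  pr <- precision_recall(list(TP = 0, FP = 0, FN = 0))
  expect_equal(unname(pr), c(0, 1))
})

test_that("average precision reproduces the worked ranking example", {
  # ranked [TP, FP, TP] with 2 ground truths
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2, "all_point"),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-9)
  expect_equal(average_precision(c(TRUE, TRUE), 2, "all_point"), 1)
  expect_equal(average_precision(c(FALSE, FALSE), 2, "all_point"), 0)
  expect_true(is.na(average_precision(logical(), 0, "all_point")))
})

test_that("MCC follows the printed formula with zero-denominator convention", {
  expect_equal(mcc_score(10, 20, 0, 0), 1)
  expect_equal(mcc_score(90, 85, 10, 15),
               7500 / sqrt(100 * 105 * 95 * 100), tolerance = 1e-9)
  expect_equal(mcc_score(90, 85, 10, 15), 0.7509, tolerance = 1e-4)
  expect_equal(mcc_score(0, 0, 5, 5), -1)  # all predictions wrong
  expect_equal(mcc_score(0, 0, 0, 5), 0)   # zero denominator factor
  # swapping (TP,FN) with (TN,FP) negates it
  expect_equal(mcc_score(15, 10, 85, 90), -mcc_score(90, 85, 10, 15),
               tolerance = 1e-12)
})

test_that("the evaluation suite is exact on perfect detections and ranks thresholds", {
  fix <- make_eval_fixture(8, seed = 9)
  perfect <- cbind(fix$gts[, 1:2], score = 1, fix$gts[, 3:6])
  rep <- map_suite(perfect, fix$gts, score_thresh = 0.5)
  expect_equal(rep$map50, 1)
  expect_equal(rep$map5095, 1)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  # uniformly ~0.6-IoU detections count at 0.5 but not at higher thresholds
  shifted <- perfect
  shifted$cx <- shifted$cx + shifted$w * 0.22
  rep2 <- map_suite(shifted, fix$gts)
  expect_gt(rep2$map50, 0.9)
  expect_lt(rep2$map5095, rep2$map50)
})

test_that("mAP is invariant to class relabeling and rank-preserving rescaling", {
  fix <- make_eval_fixture(15, seed = 13)
  base <- map_suite(fix$dets, fix$gts)
  relab <- function(x) (x + 1L) %% 3L
  d2 <- fix$dets; d2$class_id <- relab(d2$class_id)
  g2 <- fix$gts; g2$class_id <- relab(g2$class_id)
  r2 <- map_suite(d2, g2)
  expect_equal(r2$map50, base$map50, tolerance = 1e-12)
  expect_equal(r2$map5095, base$map5095, tolerance = 1e-12)
  d3 <- fix$dets; d3$score <- d3$score * 0.31
  r3 <- map_suite(d3, fix$gts, score_thresh = 0)
  expect_equal(r3$map50, base$map50, tolerance = 1e-12)
})

test_that("the suite agrees with the definition-level reference evaluator", {
  fix <- make_eval_fixture(40, seed = 421)
  expect_gte(nrow(fix$dets), 100)
  rep <- map_suite(fix$dets, fix$gts, ap_mode = "coco101")
  expect_equal(rep$map50, ref_map(fix$dets, fix$gts, 0.5, "coco101"),
               tolerance = 1e-3)
  grid <- seq(0.5, 0.95, by = 0.05)
  ref5095 <- mean(vapply(grid, function(th) ref_map(fix$dets, fix$gts, th,
                                                    "coco101"), numeric(1)))
  expect_equal(rep$map5095, ref5095, tolerance = 1e-3)
  # all-point flavour agrees too
  rep_ap <- map_suite(fix$dets, fix$gts, ap_mode = "all_point")
  expect_equal(rep_ap$map50, ref_map(fix$dets, fix$gts, 0.5, "all_point"),
               tolerance = 1e-3)
})

test_that("ROC sweeps thresholds with detection-adapted true negatives", {
  fix <- make_eval_fixture(8, seed = 17)
  cells <- 4000
  perfect <- cbind(fix$gts[, 1:2], score = 1, fix$gts[, 3:6])
  roc <- roc_curve(perfect, fix$gts, cells)
  expect_equal(roc$auc, 1)
  expect_false(roc$degenerate)
  # no detections at any threshold: flagged degenerate, endpoint AUC 0.5
  roc0 <- roc_curve(perfect[0, ], fix$gts, cells)
  expect_true(roc0$degenerate)
  expect_equal(roc0$auc, 0.5)
  # TPR never increases as the threshold rises
  noisy <- fix$dets
  roc2 <- roc_curve(noisy, fix$gts, cells)
  expect_true(all(diff(roc2$points$TPR) <= 1e-12))
  expect_true(all(roc2$points$TPR >= 0 & roc2$points$TPR <= 1))
  expect_true(all(roc2$points$FPR >= 0 & roc2$points$FPR <= 1))
})
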