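# helper: a config whose grids are easy to reason about
loss_cfg <- function() {
  detector_config(n_classes = 2L, input_size = c(320L, 320L),
                  widths = c(4L, 6L, 8L, 10L, 12L), seed = 1L)
}

# build decoded grids holding given per-cell values
decoded_grids <- function(cfg) {
  lapply(1:3, function(s) {
    S <- 320L %/% cfg$strides[s]
    array(0, c(S, S, 3L * (5L + cfg$n_classes)))
  })
}

test_that("target assignment puts a centered box in the center cell", {
  cfg <- loss_cfg()
  asg <- assign_targets(bbox(0L, 0.5, 0.5, 0.12, 0.12), cfg)
  p3 <- asg$cells[asg$cells$scale == 1, ]
  expect_true(nrow(p3) >= 1)
  expect_true(all(p3$row == 20L & p3$col == 20L))  # floor(0.5 * 40)
  # empty image: nothing responsible
  expect_equal(nrow(assign_targets(empty_boxes(), cfg)$cells), 0L)
  # every box gets at least one responsible anchor-cell, even a shape
  # far from every anchor (best-ratio fallback)
  asg2 <- assign_targets(bbox(0L, 0.5, 0.5, 0.9, 0.02), cfg)
  expect_gte(nrow(asg2$cells), 1L)
  set.seed(3)
  for (i in 1:20) {
    w <- runif(1, 0.03, 0.6); h <- runif(1, 0.03, 0.6)
    b <- bbox(0L, runif(1, w / 2, 1 - w / 2), runif(1, h / 2, 1 - h / 2), w, h)
    expect_gte(nrow(assign_targets(b, cfg)$cells), 1L)
  }
})

test_that("loss components reproduce hand-computed sums", {
  cfg <- loss_cfg()
  boxes <- bbox(0L, 0.4, 0.6, 0.1, 0.3)
  asg <- assign_targets(boxes, cfg)
  ce <- asg$cells[1, ]
  per <- 7L
  preds <- decoded_grids(cfg)
  # every other anchor-cell predicts exactly 0 -> no noobj contribution;
  # the responsible cell predicts box (0.5, 0.5, 0.2, 0.2)
  base <- (ce$anchor - 1L) * per
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 1:4] <- c(0.5, 0.5, 0.2, 0.2)
  # class probabilities match the one-hot target; confidence left at 0
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 6] <- 1
  # keep only this single responsible cell for the hand sum
  asg$cells <- asg$cells[1, , drop = FALSE]
  ls <- detection_loss(preds, asg, decoded = TRUE)
  expect_equal(ls$l_obj, (0.01 + 0.01) + (0.01 + 0.01), tolerance = 1e-6)
  expect_equal(ls$l_cls, 0, tolerance = 1e-6)
  # confidence: target is IoU(pred, gt); pred (0.5,0.5,0.2,0.2) vs
  # gt (0.4,0.6,0.1,0.3): intersection 0.05 x 0.15, union 0.0525
  iou <- (0.05 * 0.15) / (0.2 * 0.2 + 0.1 * 0.3 - 0.05 * 0.15)
  expect_equal(ls$l_conf, iou^2, tolerance = 1e-6)
})

test_that("confidence loss weights no-object cells by lambda_noobj", {
  cfg <- loss_cfg()
  boxes <- bbox(0L, 0.4, 0.6, 0.1, 0.3)
  asg <- assign_targets(boxes, cfg)
  asg$cells <- asg$cells[1, , drop = FALSE]
  ce <- asg$cells[1, ]
  per <- 7L
  preds <- decoded_grids(cfg)
  base <- (ce$anchor - 1L) * per
  # responsible cell predicts the ground truth box exactly -> IoU target 1
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 1:4] <- c(0.4, 0.6, 0.1, 0.3)
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 5] <- 0.8
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 6] <- 1
  # one arbitrary no-object cell predicts confidence 0.1
  preds[[1]][3, 3, 5] <- 0.1
  ls <- detection_loss(preds, asg, decoded = TRUE)
  expect_equal(ls$l_conf, (1 - 0.8)^2 + 0.5 * 0.1^2, tolerance = 1e-6)
  expect_equal(ls$l_obj, 0, tolerance = 1e-12)
  # perfect predictions everywhere -> every component zero
  preds[[ce$scale]][ce$row + 1, ce$col + 1, base + 5] <- 1
  preds[[1]][3, 3, 5] <- 0
  ls2 <- detection_loss(preds, asg, decoded = TRUE)
  expect_equal(ls2$l_obj + ls2$l_cls + ls2$l_conf + ls2$total, 0,
               tolerance = 1e-12)
})

test_that("the total is linear in the component weights", {
  cfg <- loss_cfg()
  set.seed(2)
  boxes <- bbox(c(0L, 1L), c(0.3, 0.7), c(0.3, 0.7), c(0.2, 0.25), c(0.2, 0.15))
  asg <- assign_targets(boxes, cfg)
  preds <- lapply(decoded_grids(cfg), function(p) array(rnorm(length(p), 0, 0.2),
                                                        dim(p)))
  for (wts in list(loss_weights(), loss_weights(box = 2, cls = 0.1, conf = 3),
                   loss_weights(box = 0, cls = 0, conf = 1, noobj = 0))) {
    ls <- detection_loss(preds, asg, weights = wts, decoded = TRUE)
    expect_equal(ls$total,
                 wts$box * ls$l_obj + wts$cls * ls$l_cls + wts$conf * ls$l_conf,
                 tolerance = 1e-9)
    expect_gte(ls$l_obj, 0); expect_gte(ls$l_cls, 0); expect_gte(ls$l_conf, 0)
  }
})

test_that("the vectorized loss equals a naive triple-loop evaluation", {
  cfg <- detector_config(n_classes = 2L, input_size = c(64L, 64L),
                         widths = c(4L, 6L, 8L, 10L, 12L), seed = 2L)
  wts <- loss_weights()
  set.seed(7)
  for (img in 1:2) {
    boxes <- bbox(c(0L, 1L), runif(2, 0.25, 0.75), runif(2, 0.25, 0.75),
                  runif(2, 0.1, 0.4), runif(2, 0.1, 0.4))
    asg <- assign_targets(boxes, cfg)
    preds <- lapply(1:3, function(s) {
      S <- 64L %/% cfg$strides[s]
      array(rnorm(S * S * 21, 0, 0.5), c(S, S, 21L))
    })
    names(preds) <- c("p3", "p4", "p5")
    ls <- detection_loss(preds, asg, wts)
    # naive reference: loop every scale/cell/anchor
    per <- 7L
    l_obj <- l_cls <- l_conf <- 0
    for (s in 1:3) {
      S <- dim(preds[[s]])[1]
      for (r0 in 0:(S - 1)) for (c0 in 0:(S - 1)) for (a in 1:3) {
        t <- preds[[s]][r0 + 1, c0 + 1, (a - 1) * per + 1:per]
        hit <- asg$cells[asg$cells$scale == s & asg$cells$row == r0 &
                         asg$cells$col == c0 & asg$cells$anchor == a, ]
        if (nrow(hit) == 0) {
          l_conf <- l_conf + wts$noobj * t[5]^2
        } else {
          gt <- boxes[hit$gt[1], ]
          aw <- cfg$anchors[[s]][a, 1]; ah <- cfg$anchors[[s]][a, 2]
          px <- (c0 + plogis(t[1])) / S; py <- (r0 + plogis(t[2])) / S
          pw <- (2 * plogis(t[3]))^2 * aw / 64
          ph <- (2 * plogis(t[4]))^2 * ah / 64
          l_obj <- l_obj + (px - gt$cx)^2 + (py - gt$cy)^2 +
                   (pw - gt$w)^2 + (ph - gt$h)^2
          iou <- ref_iou(c(px - pw / 2, py - ph / 2, px + pw / 2, py + ph / 2),
                         c(gt$cx - gt$w / 2, gt$cy - gt$h / 2,
                           gt$cx + gt$w / 2, gt$cy + gt$h / 2))
          l_conf <- l_conf + (iou - t[5])^2
          onehot <- as.numeric(0:1 == gt$class_id)
          l_cls <- l_cls + sum((onehot - plogis(t[6:7]))^2)
        }
      }
    }
    expect_equal(ls$l_obj, l_obj, tolerance = 1e-6)
    expect_equal(ls$l_cls, l_cls, tolerance = 1e-6)
    expect_equal(ls$l_conf, l_conf, tolerance = 1e-6)
  }
})

test_that("loss gradients match finite differences on raw grids", {
  cfg <- detector_config(n_classes = 2L, input_size = c(64L, 64L),
                         widths = c(4L, 6L, 8L, 10L, 12L), seed = 2L)
  set.seed(11)
  boxes <- bbox(c(0L, 1L), c(0.3, 0.65), c(0.4, 0.6), c(0.2, 0.3), c(0.25, 0.2))
  asg <- assign_targets(boxes, cfg)
  preds <- lapply(1:3, function(s) {
    S <- 64L %/% cfg$strides[s]
    array(rnorm(S * S * 21, 0, 0.5), c(S, S, 21L))
  })
  names(preds) <- c("p3", "p4", "p5")
  for (mode in c("sse", "ciou")) {
    ls <- detection_loss(preds, asg, box_mode = mode, with_grad = TRUE)
    ct <- ls$conf_targets
    # probe responsible cells (all channels) and a few background cells
    probes <- list()
    cc <- asg$cells
    for (r in seq_len(min(4, nrow(cc)))) {
      for (ch in 1:7) {
        probes[[length(probes) + 1]] <-
          c(cc$scale[r], cc$row[r] + 1, cc$col[r] + 1,
            (cc$anchor[r] - 1) * 7 + ch)
      }
    }
    probes[[length(probes) + 1]] <- c(1, 1, 1, 5)
    probes[[length(probes) + 1]] <- c(2, 2, 2, 12)
    for (p in probes) {
      eps <- 1e-6
      up <- preds; up[[p[1]]][p[2], p[3], p[4]] <- up[[p[1]]][p[2], p[3], p[4]] + eps
      dn <- preds; dn[[p[1]]][p[2], p[3], p[4]] <- dn[[p[1]]][p[2], p[3], p[4]] - eps
      fd <- (detection_loss(up, asg, box_mode = mode, conf_targets = ct)$total -
             detection_loss(dn, asg, box_mode = mode, conf_targets = ct)$total) /
            (2 * eps)
      an <- ls$grads[[p[1]]][p[2], p[3], p[4]]
      expect_equal(an, fd, tolerance = max(1e-3, 1e-3 * abs(fd)),
                   label = sprintf("grad %s scale %d ch %d", mode, p[1], p[4]))
    }
  }
})

test_that("non-finite predictions are reported with their location", {
  cfg <- loss_cfg()
  asg <- assign_targets(bbox(0L, 0.5, 0.5, 0.2, 0.2), cfg)
  preds <- decoded_grids(cfg)
  preds[[2]][1, 2, 3] <- NaN
  expect_error(detection_loss(preds, asg, decoded = TRUE), "scale 2")
})
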