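# Independent reference implementations used as oracles. These are written
# directly from definitions (explicit loops, no shared code with the
# package) so that package results can be checked against a second route.

# Plain IoU of two corner boxes, written independently.
ref_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (u <= 0) 0 else inter / u
}

# O(n^2) brute-force greedy NMS over one class/image group: a detection
# survives iff no higher-ranked survivor of its group overlaps it.
ref_nms <- function(dets, thresh) {
  ord <- order(-dets$score, dets$cx, dets$cy, dets$w, dets$h, dets$class_id)
  dets <- dets[ord, , drop = FALSE]
  n <- nrow(dets)
  alive <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !alive[j]) next
      if (dets$class_id[j] != dets$class_id[i] ||
          dets$image_id[j] != dets$image_id[i]) next
      a <- c(dets$cx[i] - dets$w[i] / 2, dets$cy[i] - dets$h[i] / 2,
             dets$cx[i] + dets$w[i] / 2, dets$cy[i] + dets$h[i] / 2)
      b <- c(dets$cx[j] - dets$w[j] / 2, dets$cy[j] - dets$h[j] / 2,
             dets$cx[j] + dets$w[j] / 2, dets$cy[j] + dets$h[j] / 2)
      if (ref_iou(a, b) >= thresh) alive[j] <- FALSE
    }
  }
  dets[alive, , drop = FALSE]
}

# Definition-level evaluator: greedy score-ordered matching, cumulative
# precision/recall, and AP by direct interpolation loops. Returns the mean
# AP over classes with ground truth at one IoU threshold.
ref_map <- function(dets, gts, iou_thresh, mode = c("coco101", "all_point")) {
  mode <- match.arg(mode)
  aps <- c()
  for (cl in sort(unique(gts$class_id))) {
    d <- dets[dets$class_id == cl, , drop = FALSE]
    d <- d[order(-d$score, d$cx, d$cy, d$w, d$h), , drop = FALSE]
    g <- gts[gts$class_id == cl, , drop = FALSE]
    n_gt <- nrow(g)
    if (n_gt == 0) next
    taken <- rep(FALSE, n_gt)
    tp <- numeric(nrow(d))
    for (i in seq_len(nrow(d))) {
      best <- 0; best_j <- 0
      for (j in seq_len(n_gt)) {
        if (taken[j] || g$image_id[j] != d$image_id[i]) next
        ov <- ref_iou(c(d$cx[i] - d$w[i]/2, d$cy[i] - d$h[i]/2,
                        d$cx[i] + d$w[i]/2, d$cy[i] + d$h[i]/2),
                      c(g$cx[j] - g$w[j]/2, g$cy[j] - g$h[j]/2,
                        g$cx[j] + g$w[j]/2, g$cy[j] + g$h[j]/2))
        if (ov > best) { best <- ov; best_j <- j }
      }
      if (best >= iou_thresh) { tp[i] <- 1; taken[best_j] <- TRUE }
    }
    cum_tp <- cumsum(tp)
    prec <- cum_tp / seq_along(tp)
    rec <- cum_tp / n_gt
    if (mode == "coco101") {
      q <- numeric(101)
      for (k in 0:100) {
        r <- k / 100
        pbest <- 0
        for (i in seq_along(rec)) {
          if (rec[i] >= r - 1e-9 && prec[i] > pbest) {
            pm <- max(prec[i:length(prec)])
            if (pm > pbest) pbest <- pm
          }
        }
        q[k + 1] <- pbest
      }
      aps <- c(aps, mean(q))
    } else {
      ap <- 0
      prev_r <- 0
      for (i in seq_along(rec)) {
        if (tp[i] == 1) {
          ap <- ap + (rec[i] - prev_r) * max(prec[i:length(prec)])
          prev_r <- rec[i]
        }
      }
      aps <- c(aps, ap)
    }
  }
  mean(aps)
}

# Deterministic random detection/ground-truth fixture: n_img images,
# 3 classes, jittered true positives plus false positives.
make_eval_fixture <- function(n_img = 30, seed = 421) {
  set.seed(seed)
  gts <- list(); dets <- list()
  for (i in seq_len(n_img)) {
    id <- sprintf("im%03d", i)
    for (b in seq_len(sample(1:4, 1))) {
      cl <- sample(0:2, 1)
      w <- runif(1, 0.1, 0.3); h <- runif(1, 0.1, 0.3)
      cx <- runif(1, w / 2, 1 - w / 2); cy <- runif(1, h / 2, 1 - h / 2)
      gts[[length(gts) + 1]] <- data.frame(image_id = id, class_id = cl,
                                           cx = cx, cy = cy, w = w, h = h)
      if (runif(1) < 0.85) {  # jittered detection of this box
        j <- rnorm(4, 0, c(0.02, 0.02, 0.03, 0.03))
        dets[[length(dets) + 1]] <- data.frame(
          image_id = id, class_id = if (runif(1) < 0.9) cl else sample(0:2, 1),
          score = runif(1, 0.05, 1),
          cx = min(max(cx + j[1], 0.05), 0.95),
          cy = min(max(cy + j[2], 0.05), 0.95),
          w = max(w * (1 + j[3]), 0.02), h = max(h * (1 + j[4]), 0.02))
      }
    }
    for (f in seq_len(sample(0:3, 1))) {  # false positives
      w <- runif(1, 0.05, 0.25); h <- runif(1, 0.05, 0.25)
      dets[[length(dets) + 1]] <- data.frame(
        image_id = id, class_id = sample(0:2, 1), score = runif(1, 0.05, 0.8),
        cx = runif(1, w / 2, 1 - w / 2), cy = runif(1, h / 2, 1 - h / 2),
        w = w, h = h)
    }
  }
  list(dets = do.call(rbind, dets), gts = do.call(rbind, gts))
}

# Tiny slide spec used across tests (fast to render).
tiny_spec <- function(...) {
  args <- list(n_classes = 2L, image_size = c(96L, 96L),
               cells_per_image = c(1L, 3L), class_weights = c(0.6, 0.4),
               blur_sigma = c(0, 0.8), seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(slide_spec, args)
}
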