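# Split-recombine augmentation: cut two annotated images into halves,
# stitch mixed-source halves into four new images with exactly remapped
# labels, plus mirror/translate/rotate ops and a class-balancing driver.
# All box remapping is exact in normalized coordinates (no resampling), so
# label geometry survives every op with IoU 1 against the pixel transform.

#' Augmentation policy
#'
#' @param clip_keep_fraction Minimum retained-area fraction for a box
#'   crossing a cut or frame edge; smaller remnants are dropped. Partially
#'   visible cells are a deliberate feature of the augmentation (they mimic
#'   edge-truncated cells in real micrographs), so remnants above this
#'   fraction are kept and clipped rather than discarded.
#' @param balance_ratio Target minimum ratio of the rarest class's box
#'   count to the most frequent class's box count.
#' @param ops Geometric ops the balancing driver may add on top of
#'   recombination.
#' @param budget Maximum number of image pairs the driver may consume.
#' @param orientation `"vertical"` cuts into left/right halves,
#'   `"horizontal"` into top/bottom.
#' @param seed RNG seed for the driver.
#' @return An object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(clip_keep_fraction = 0.2, balance_ratio = 0.5,
                                ops = c("mirror", "translate", "rotate"),
                                budget = 200L, orientation = "vertical",
                                seed = 1L) {
  stopifnot(clip_keep_fraction > 0, clip_keep_fraction <= 1,
            balance_ratio > 0, balance_ratio <= 1)
  orientation <- match.arg(orientation, c("vertical", "horizontal"))
  structure(list(clip_keep_fraction = clip_keep_fraction,
                 balance_ratio = balance_ratio, ops = ops,
                 budget = as.integer(budget), orientation = orientation,
                 seed = as.integer(seed)),
            class = "augmentation_policy")
}

# Clip corner-form pixel boxes to a [lo, hi] range along one axis, keeping a
# box only when the retained area fraction is >= keep. Returns the clipped
# corner matrix plus the surviving row indices.
clip_axis <- function(corners, axis, lo, hi, keep) {
  if (nrow(corners) == 0L) return(list(corners = corners, keep = integer()))
  c1 <- corners[, axis]; c2 <- corners[, axis + 2L]
  n1 <- pmax(c1, lo); n2 <- pmin(c2, hi)
  frac <- pmax(0, n2 - n1) / (c2 - c1)
  sel <- which(frac >= keep & n2 > n1)
  out <- corners[sel, , drop = FALSE]
  out[, axis] <- pmax(c1[sel], lo)
  out[, axis + 2L] <- pmin(c2[sel], hi)
  list(corners = out, keep = sel)
}

#' Split an annotated image into two halves
#'
#' Cuts the raster at `floor(W/2)` (vertical orientation; left/right) or
#' `floor(H/2)` (horizontal; top/bottom). Each box is assigned to the
#' half(s) it overlaps; a box crossing the cut is clipped to each side and
#' kept only where its retained-area fraction is at least
#' `clip_keep_fraction`; surviving boxes are re-normalized to the half's own
#' frame. The two halves' pixels concatenate back to the input exactly.
#'
#' @param img An [annotated_image()].
#' @param clip_keep_fraction See [augmentation_policy()].
#' @param orientation `"vertical"` or `"horizontal"`.
#' @return A list of two `image_half` objects.
#' @export
split_image <- function(img, clip_keep_fraction = 0.2,
                        orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  d <- dim(img$pixels); H <- d[1]; W <- d[2]
  corners <- boxes_to_corners(img$boxes)
  if (orientation == "vertical") {
    stopifnot(W >= 2)
    cut <- floor(W / 2)
    cpx <- corners
    cpx[, c(1, 3)] <- cpx[, c(1, 3)] * W
    cpx[, c(2, 4)] <- cpx[, c(2, 4)] * H
    mk <- function(lo, hi) {
      cl <- clip_axis(cpx, 1L, lo, hi, clip_keep_fraction)
      cc <- cl$corners
      if (nrow(cc)) {
        cc[, c(1, 3)] <- (cc[, c(1, 3)] - lo) / (hi - lo)
        cc[, c(2, 4)] <- cc[, c(2, 4)] / H
      }
      corners_to_boxes(cc, img$boxes$class_id[cl$keep])
    }
    left <- structure(list(pixels = img$pixels[, 1:cut, , drop = FALSE],
                           boxes = mk(0, cut),
                           origin = list(source = img$image_id, side = "left"),
                           orientation = orientation), class = "image_half")
    right <- structure(list(pixels = img$pixels[, (cut + 1):W, , drop = FALSE],
                            boxes = mk(cut, W),
                            origin = list(source = img$image_id, side = "right"),
                            orientation = orientation), class = "image_half")
    list(left, right)
  } else {
    stopifnot(H >= 2)
    cut <- floor(H / 2)
    cpx <- corners
    cpx[, c(1, 3)] <- cpx[, c(1, 3)] * W
    cpx[, c(2, 4)] <- cpx[, c(2, 4)] * H
    mk <- function(lo, hi) {
      cl <- clip_axis(cpx, 2L, lo, hi, clip_keep_fraction)
      cc <- cl$corners
      if (nrow(cc)) {
        cc[, c(2, 4)] <- (cc[, c(2, 4)] - lo) / (hi - lo)
        cc[, c(1, 3)] <- cc[, c(1, 3)] / W
      }
      corners_to_boxes(cc, img$boxes$class_id[cl$keep])
    }
    top <- structure(list(pixels = img$pixels[1:cut, , , drop = FALSE],
                          boxes = mk(0, cut),
                          origin = list(source = img$image_id, side = "top"),
                          orientation = orientation), class = "image_half")
    bottom <- structure(list(pixels = img$pixels[(cut + 1):H, , , drop = FALSE],
                             boxes = mk(cut, H),
                             origin = list(source = img$image_id, side = "bottom"),
                             orientation = orientation), class = "image_half")
    list(top, bottom)
  }
}

#' Recombine two image halves into a new annotated image
#'
#' Places `first` on the left (or top) and `second` on the right (or
#' bottom), re-normalizing both halves' boxes into the combined frame.
#'
#' @param first,second `image_half` objects of matching height (vertical)
#'   or width (horizontal).
#' @param image_id Id for the combined image.
#' @return An [annotated_image()].
#' @export
recombine_halves <- function(first, second, image_id = NULL) {
  vert <- identical(first$orientation, "vertical")
  d1 <- dim(first$pixels); d2 <- dim(second$pixels)
  if (is.null(image_id)) {
    image_id <- paste0(first$origin$source, "-", first$origin$side, "+",
                       second$origin$source, "-", second$origin$side)
  }
  if (vert) {
    if (d1[1] != d2[1]) stop("shape error: half heights differ (",
                             d1[1], " vs ", d2[1], ")")
    H <- d1[1]; w1 <- d1[2]; w2 <- d2[2]; W <- w1 + w2
    px <- array(0, c(H, W, 3))
    px[, 1:w1, ] <- first$pixels
    px[, (w1 + 1):W, ] <- second$pixels
    b1 <- first$boxes; b2 <- second$boxes
    if (nrow(b1)) { b1$cx <- b1$cx * w1 / W; b1$w <- b1$w * w1 / W }
    if (nrow(b2)) { b2$cx <- (w1 + b2$cx * w2) / W; b2$w <- b2$w * w2 / W }
    annotated_image(px, rbind(b1, b2), image_id)
  } else {
    if (d1[2] != d2[2]) stop("shape error: half widths differ (",
                             d1[2], " vs ", d2[2], ")")
    W <- d1[2]; h1 <- d1[1]; h2 <- d2[1]; H <- h1 + h2
    px <- array(0, c(H, W, 3))
    px[1:h1, , ] <- first$pixels
    px[(h1 + 1):H, , ] <- second$pixels
    b1 <- first$boxes; b2 <- second$boxes
    if (nrow(b1)) { b1$cy <- b1$cy * h1 / H; b1$h <- b1$h * h1 / H }
    if (nrow(b2)) { b2$cy <- (h1 + b2$cy * h2) / H; b2$h <- b2$h * h2 / H }
    annotated_image(px, rbind(b1, b2), image_id)
  }
}

#' Split two images and recombine into four mixed-source images
#'
#' Each input is cut into two halves; the four ordered mixed-source
#' recombinations `(aL,bR)`, `(bL,aR)`, `(aR,bL)`, `(bR,aL)` are returned.
#' Same-source pairs are never produced, so every output differs from both
#' inputs. Across the four outputs each half is used exactly twice, hence
#' total box count equals twice the boxes surviving the two splits.
#'
#' @param imgA,imgB [annotated_image()]s of identical dimensions with
#'   differing pixel content.
#' @param clip_keep_fraction See [augmentation_policy()].
#' @param orientation Cut orientation.
#' @return A list of exactly four [annotated_image()]s.
#' @export
split_recombine_pair <- function(imgA, imgB, clip_keep_fraction = 0.2,
                                 orientation = c("vertical", "horizontal")) {
  orientation <- match.arg(orientation)
  if (!identical(dim(imgA$pixels), dim(imgB$pixels))) {
    stop("shape error: images must share dimensions")
  }
  if (identical(imgA$pixels, imgB$pixels)) {
    stop("distinctness violation: the two source images are pixel-identical, ",
         "no recombination can differ from the originals")
  }
  ha <- split_image(imgA, clip_keep_fraction, orientation)
  hb <- split_image(imgB, clip_keep_fraction, orientation)
  list(recombine_halves(ha[[1]], hb[[2]]),
       recombine_halves(hb[[1]], ha[[2]]),
       recombine_halves(ha[[2]], hb[[1]]),
       recombine_halves(hb[[2]], ha[[1]]))
}

#' Geometric augmentation with exact box remapping
#'
#' Mirror (horizontal flip), translate by integer-pixel fractions, or
#' rotate by a multiple of 90 degrees (clockwise). Boxes are transformed
#' with the pixels; boxes pushed (partly) out of the frame by translation
#' are clipped under the `clip_keep_fraction` rule. `mirror` composed with
#' itself is the identity; rotations keep axis-aligned boxes tight.
#'
#' @param img An [annotated_image()].
#' @param op One of `"mirror"`, `"translate"`, `"rotate"`.
#' @param params For translate: `list(dx=, dy=)` fractions of image size.
#'   For rotate: `list(angle=)`, a multiple of 90.
#' @param clip_keep_fraction See [augmentation_policy()].
#' @return An [annotated_image()].
#' @export
geometric_augment <- function(img, op = c("mirror", "translate", "rotate"),
                              params = list(), clip_keep_fraction = 0.2) {
  op <- match.arg(op)
  d <- dim(img$pixels); H <- d[1]; W <- d[2]
  if (op == "mirror") {
    px <- img$pixels[, W:1, , drop = FALSE]
    b <- img$boxes
    if (nrow(b)) b$cx <- 1 - b$cx
    return(annotated_image(px, b, paste0(img$image_id, "_mir")))
  }
  if (op == "rotate") {
    angle <- params$angle %||% 90
    if (angle %% 90 != 0) stop("parameter error: rotation must be a multiple of 90 degrees")
    k <- as.integer((angle / 90) %% 4)
    px <- img$pixels; b <- img$boxes
    for (t in seq_len(k)) {
      # 90 degrees clockwise: (x, y) -> (1 - y, x); raster H x W -> W x H
      px <- aperm(px[dim(px)[1]:1, , , drop = FALSE], c(2, 1, 3))
      if (nrow(b)) {
        b <- data.frame(class_id = b$class_id, cx = 1 - b$cy, cy = b$cx,
                        w = b$h, h = b$w)
      }
    }
    return(annotated_image(px, b, paste0(img$image_id, "_rot", k * 90)))
  }
  # translate
  dx <- params$dx %||% 0; dy <- params$dy %||% 0
  sx <- round(dx * W); sy <- round(dy * H)
  fill <- mean(img$pixels)
  px <- array(fill, c(H, W, 3))
  src_r <- intersect(seq_len(H), seq_len(H) - sy)
  src_c <- intersect(seq_len(W), seq_len(W) - sx)
  if (length(src_r) && length(src_c)) {
    px[src_r + sy, src_c + sx, ] <- img$pixels[src_r, src_c, , drop = FALSE]
  }
  corners <- boxes_to_corners(img$boxes)
  if (nrow(corners)) {
    corners[, c(1, 3)] <- corners[, c(1, 3)] + sx / W
    corners[, c(2, 4)] <- corners[, c(2, 4)] + sy / H
  }
  cl <- clip_axis(corners, 1L, 0, 1, clip_keep_fraction)
  keep1 <- cl$keep
  cl2 <- clip_axis(cl$corners, 2L, 0, 1, clip_keep_fraction)
  b <- corners_to_boxes(cl2$corners, img$boxes$class_id[keep1][cl2$keep])
  annotated_image(px, b, paste0(img$image_id, "_tr"))
}

#' Balance a dataset by minority-biased split-recombine augmentation
#'
#' Repeatedly samples an image containing the currently rarest class and a
#' random partner, applies [split_recombine_pair()] (plus a random
#' geometric op per output), and appends the results to the dataset until
#' every class's box count reaches `balance_ratio` times the most frequent
#' class's count, or the pair budget is exhausted (in which case the
#' returned index carries a warning status rather than an error).
#' Deterministic under `policy$seed`.
#'
#' @param index A `dataset_index`.
#' @param policy An [augmentation_policy()].
#' @param out_dir Where augmented files are written (defaults to the
#'   dataset's own directory).
#' @return The augmented `dataset_index`.
#' @export
balance_dataset <- function(index, policy = augmentation_policy(),
                            out_dir = index$dir) {
  stopifnot(inherits(index, "dataset_index"), nrow(index$files) >= 2L,
            sum(index$class_counts) >= 1L)
  counts <- index$class_counts
  target_met <- function(cnt) min(cnt) >= policy$balance_ratio * max(cnt)
  if (target_met(counts)) return(index)
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  # per-image class presence for minority-biased sampling
  presence <- lapply(index$files$label, function(p) {
    unique(read_yolo_labels(p)$class_id)
  })
  files <- index$files
  status <- "ok"
  with_seed(policy$seed, {
    budget <- policy$budget
    aug_n <- 0L
    while (!target_met(counts) && budget > 0L) {
      budget <- budget - 1L
      minority <- which.min(counts) - 1L
      cand <- which(vapply(presence, function(cl) minority %in% cl, logical(1)))
      if (!length(cand)) { status <- "warning: minority class absent"; break }
      ia <- cand[sample.int(length(cand), 1L)]
      ib <- sample.int(nrow(files), 1L)
      if (ib == ia) ib <- (ib %% nrow(files)) + 1L
      A <- load_annotated(list(files = files), ia)
      B <- load_annotated(list(files = files), ib)
      if (!identical(dim(A$pixels), dim(B$pixels)) ||
          identical(A$pixels, B$pixels)) next
      outs <- split_recombine_pair(A, B, policy$clip_keep_fraction,
                                   policy$orientation)
      for (o in outs) {
        if (length(policy$ops)) {
          op <- policy$ops[sample.int(length(policy$ops), 1L)]
          pr <- switch(op,
                       mirror = list(),
                       rotate = list(angle = 90 * sample.int(3L, 1L)),
                       translate = list(dx = runif(1, -0.15, 0.15),
                                        dy = runif(1, -0.15, 0.15)))
          o <- geometric_augment(o, op, pr, policy$clip_keep_fraction)
        }
        aug_n <- aug_n + 1L
        id <- sprintf("aug_%06d", aug_n)
        ip <- file.path(img_dir, paste0(id, ".png"))
        lp <- file.path(lab_dir, paste0(id, ".txt"))
        png::writePNG(o$pixels, ip)
        write_yolo_labels(o$boxes, lp)
        files <- rbind(files, data.frame(image_id = id, image = ip, label = lp,
                                         n_boxes = nrow(o$boxes)))
        presence[[length(presence) + 1L]] <- unique(o$boxes$class_id)
        if (nrow(o$boxes)) {
          counts <- counts + tabulate(o$boxes$class_id + 1L,
                                      nbins = index$n_classes)
        }
      }
    }
    if (!target_met(counts) && status == "ok") {
      status <- "warning: augmentation budget exhausted before balance target"
    }
  })
  out <- index
  out$files <- files
  out$class_counts <- counts
  out$status <- status
  out
}
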