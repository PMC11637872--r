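# Bounding boxes travel as data frames with columns
# class_id (0-based integer), cx, cy, w, h -- all coordinates normalized to
# the image frame: centers in [0,1], extents in (0,1]. Corner form is
# (x1, y1, x2, y2), also normalized, x1 < x2 and y1 < y2.

#' Construct a normalized bounding-box table
#'
#' Boxes use the YOLO center convention: `cx`, `cy` locate the box center and
#' `w`, `h` its full extent, all as fractions of the image dimensions.
#'
#' @param class_id Integer vector of 0-based class ids.
#' @param cx,cy Box centers in `[0, 1]`.
#' @param w,h Box extents in `(0, 1]`.
#' @return A `data.frame` with columns `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
#' @examples
#' bbox(0L, 0.5, 0.5, 0.2, 0.3)
bbox <- function(class_id = integer(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric()) {
  out <- data.frame(class_id = as.integer(class_id), cx = as.numeric(cx),
                    cy = as.numeric(cy), w = as.numeric(w), h = as.numeric(h))
  validate_boxes(out)
  out
}

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric())
}

#' Validate a bounding-box table
#'
#' Checks the box invariants: centers in `[0,1]`, extents in `(0,1]`,
#' non-empty intersection of the box with the unit frame, and (optionally)
#' class ids below `n_classes`.
#'
#' @param boxes A box `data.frame` as returned by [bbox()].
#' @param n_classes Optional class count to check ids against.
#' @return `boxes`, invisibly. Errors describe the offending box.
#' @export
validate_boxes <- function(boxes, n_classes = NULL) {
  stopifnot(is.data.frame(boxes))
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!all(need %in% names(boxes))) {
    stop("box table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(boxes) == 0L) return(invisible(boxes))
  with(boxes, {
    if (any(class_id < 0L)) stop("validation error: negative class_id")
    if (!is.null(n_classes) && any(class_id >= n_classes)) {
      stop("validation error: class_id >= n_classes (", n_classes, ")")
    }
    if (any(cx < 0 | cx > 1 | cy < 0 | cy > 1)) {
      stop("validation error: box center outside [0,1]")
    }
    if (any(w <= 0 | w > 1 | h <= 0 | h > 1)) {
      stop("validation error: box extent outside (0,1]")
    }
    if (any(cx + w / 2 <= 0 | cx - w / 2 >= 1 | cy + h / 2 <= 0 | cy - h / 2 >= 1)) {
      stop("validation error: box does not intersect the image frame")
    }
  })
  invisible(boxes)
}

#' Convert center-format boxes to corner format
#'
#' @param boxes A box `data.frame` (center format).
#' @return A numeric matrix with columns `x1`, `y1`, `x2`, `y2`.
#' @export
boxes_to_corners <- function(boxes) {
  m <- cbind(x1 = boxes$cx - boxes$w / 2, y1 = boxes$cy - boxes$h / 2,
             x2 = boxes$cx + boxes$w / 2, y2 = boxes$cy + boxes$h / 2)
  m
}

#' Convert corner-format boxes to center format
#'
#' @param corners Matrix with columns `x1`, `y1`, `x2`, `y2`.
#' @param class_id Integer vector of class ids (recycled).
#' @return A box `data.frame` in center format.
#' @export
corners_to_boxes <- function(corners, class_id = 0L) {
  corners <- rbind(corners)
  data.frame(class_id = as.integer(rep_len(class_id, nrow(corners))),
             cx = (corners[, 1] + corners[, 3]) / 2,
             cy = (corners[, 2] + corners[, 4]) / 2,
             w = corners[, 3] - corners[, 1],
             h = corners[, 4] - corners[, 2])
}

#' Intersection over union of two boxes
#'
#' Plain IoU of two axis-aligned boxes in corner form `(x1, y1, x2, y2)`.
#' Degenerate (zero-area) boxes give 0.
#'
#' @param a,b Numeric length-4 vectors `(x1, y1, x2, y2)`.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
box_iou <- function(a, b) {
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (area_a <= 0 || area_b <= 0) return(0)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

#' Complete IoU (CIoU) of two boxes
#'
#' IoU penalized by normalized center distance and aspect-ratio mismatch:
#' `CIoU = IoU - rho^2 / c^2 - alpha * v`, where `rho` is the center
#' distance, `c` the diagonal of the smallest enclosing box,
#' `v = (4 / pi^2) (atan(wA/hA) - atan(wB/hB))^2` and
#' `alpha = v / (1 - IoU + v)`. Equal to IoU when the boxes share center
#' and aspect ratio.
#'
#' @inheritParams box_iou
#' @return CIoU in `(-1, 1]`.
#' @export
box_ciou <- function(a, b) {
  i <- box_iou(a, b)
  wa <- a[3] - a[1]; ha <- a[4] - a[2]
  wb <- b[3] - b[1]; hb <- b[4] - b[2]
  if (wa <= 0 || ha <= 0 || wb <= 0 || hb <= 0) return(0)
  rho2 <- ((a[1] + a[3]) / 2 - (b[1] + b[3]) / 2)^2 +
          ((a[2] + a[4]) / 2 - (b[2] + b[4]) / 2)^2
  cw <- max(a[3], b[3]) - min(a[1], b[1])
  ch <- max(a[4], b[4]) - min(a[2], b[2])
  c2 <- cw^2 + ch^2
  v <- (4 / pi^2) * (atan(wa / ha) - atan(wb / hb))^2
  alpha <- if (v == 0) 0 else v / (1 - i + v)
  i - rho2 / c2 - alpha * v
}

# Vectorized IoU of one box against a corner matrix.
iou_one_vs_many <- function(a, m) {
  if (is.null(dim(m))) m <- rbind(m)
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  areas <- pmax(0, m[, 3] - m[, 1]) * pmax(0, m[, 4] - m[, 2])
  iw <- pmin(a[3], m[, 3]) - pmax(a[1], m[, 1])
  ih <- pmin(a[4], m[, 4]) - pmax(a[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  denom <- area_a + areas - inter
  out <- ifelse(denom > 0 & area_a > 0 & areas > 0, inter / denom, 0)
  as.numeric(out)
}
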