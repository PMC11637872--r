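# Deterministic synthetic "slide" generator. Real powder micrograph
# collections of medicinal herbs are not publicly available; this module
# emulates their statistical structure -- nine feature-cell classes with a
# heavy-tailed class imbalance, few small cells per image, cells truncated
# by the frame edge, and whole-image blur -- so that augmentation, training
# and evaluation are all exercisable end to end.

#' Reference annotation profile for powdered-herb feature cells
#'
#' Per-class image and box counts of a two-species herbal powder micrograph
#' annotation campaign covering nine diagnostic feature-cell types (fibers,
#' stone cells, oil cells, phloem fibers, cork cells, vessels, xylary fibers
#' and starch granules). The profile is heavily imbalanced (13 to 7555
#' images per class; 11060 images and 12840 boxes in total) and is the
#' default class-frequency shape of [slide_spec()].
#'
#' @format A `data.frame` with columns `cell_type`, `images`, `boxes`.
#' @export
cell_profile <- data.frame(
  cell_type = c("fibers", "stone_cells_mo", "oil_cells", "phloem_fibers",
                "stone_cells_sb", "cork_cells", "vessels", "xylary_fibers",
                "starch_granules"),
  images = c(7555L, 1662L, 576L, 304L, 156L, 550L, 229L, 13L, 15L),
  boxes  = c(9080L, 1726L, 644L, 353L, 171L, 580L, 257L, 13L, 16L)
)

#' Specification of a synthetic slide dataset
#'
#' Collects every knob of the generator. Defaults emulate the reference
#' annotation profile: 9 classes with the [cell_profile] image-count shape,
#' 320x320 images (divisible by the network stride 32), 0--5 cells per
#' image, whole-image Gaussian blur up to sigma 1.5 px, and a quarter of the
#' cells truncated by the frame edge.
#'
#' @param n_classes Number of feature-cell classes.
#' @param image_size `(H, W)` in pixels; both must be >= 32 and divisible
#'   by 32.
#' @param cells_per_image Inclusive integer range `(min, max)` of cells per
#'   image.
#' @param class_weights Probability vector of length `n_classes`
#'   (must sum to 1). Default: the [cell_profile] image counts normalized,
#'   truncated/renormalized when `n_classes < 9`.
#' @param blur_sigma Range of the whole-image Gaussian blur sigma in pixels.
#' @param edge_truncation_prob Fraction of cells placed across the frame
#'   edge so only part of the cell is visible.
#' @param cell_size Range of the cell's major semi-axis as a fraction of the
#'   shorter image side.
#' @param seed Root seed; image `i` uses stream `seed + i`.
#' @return An object of class `slide_spec`.
#' @export
slide_spec <- function(n_classes = 9L,
                       image_size = c(320L, 320L),
                       cells_per_image = c(0L, 5L),
                       class_weights = NULL,
                       blur_sigma = c(0, 1.5),
                       edge_truncation_prob = 0.25,
                       cell_size = c(0.07, 0.16),
                       seed = 1L) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 1) {
    stop("configuration error in field 'n_classes': must be a positive integer")
  }
  n_classes <- as.integer(n_classes)
  if (length(image_size) != 2L || any(image_size < 32) ||
      any(image_size %% 32 != 0)) {
    stop("configuration error in field 'image_size': H and W must be >= 32 ",
         "and divisible by 32")
  }
  if (length(cells_per_image) != 2L || cells_per_image[1] > cells_per_image[2] ||
      any(cells_per_image < 0)) {
    stop("configuration error in field 'cells_per_image': need a non-empty ",
         "non-negative range")
  }
  if (is.null(class_weights)) {
    w <- cell_profile$images[seq_len(min(n_classes, nrow(cell_profile)))]
    if (n_classes > nrow(cell_profile)) {
      w <- c(w, rep(min(w), n_classes - nrow(cell_profile)))
    }
    class_weights <- w / sum(w)
  }
  if (length(class_weights) != n_classes ||
      abs(sum(class_weights) - 1) > 1e-9 || any(class_weights < 0)) {
    stop("configuration error in field 'class_weights': must be a length-",
         n_classes, " probability vector summing to 1")
  }
  if (length(blur_sigma) != 2L || blur_sigma[1] > blur_sigma[2] ||
      any(blur_sigma < 0)) {
    stop("configuration error in field 'blur_sigma': need a non-empty ",
         "non-negative range")
  }
  if (edge_truncation_prob < 0 || edge_truncation_prob > 1) {
    stop("configuration error in field 'edge_truncation_prob': must be in [0,1]")
  }
  if (length(cell_size) != 2L || cell_size[1] > cell_size[2] ||
      cell_size[1] <= 0 || cell_size[2] > 0.45) {
    stop("configuration error in field 'cell_size': need a range in (0, 0.45]")
  }
  structure(list(n_classes = n_classes,
                 image_size = as.integer(image_size),
                 cells_per_image = as.integer(cells_per_image),
                 class_weights = as.numeric(class_weights),
                 blur_sigma = as.numeric(blur_sigma),
                 edge_truncation_prob = edge_truncation_prob,
                 cell_size = as.numeric(cell_size),
                 seed = as.integer(seed)),
            class = "slide_spec")
}

#' Construct an annotated image
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 1]`.
#' @param boxes A box `data.frame` (see [bbox()]).
#' @param image_id Character id.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(pixels, boxes = empty_boxes(), image_id = "img") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  validate_boxes(boxes)
  structure(list(pixels = pixels, boxes = boxes,
                 image_id = as.character(image_id)),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<annotated_image '%s': %dx%d px, %d box(es)>\n",
              x$image_id, d[1], d[2], nrow(x$boxes)))
  invisible(x)
}

# Deterministic per-class rendering style: a base RGB color spread around
# the hue circle, an aspect-ratio range and a texture family. No RNG here.
class_style <- function(class_id, n_classes) {
  hue <- (class_id %% n_classes) / max(n_classes, 1)
  base <- grDevices::hsv(hue, s = 0.55, v = 0.55)
  rgb <- as.numeric(grDevices::col2rgb(base)) / 255
  list(color = rgb,
       aspect = switch((class_id %% 3) + 1, c(1, 1.4), c(1.6, 2.6), c(1.1, 2)),
       texture = c("speckle", "stripe", "ring")[(class_id %% 3) + 1])
}

# Separable Gaussian blur via the package's own conv kernel, per channel.
blur_image <- function(px, sigma) {
  if (sigma <= 0.05) return(px)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- 2L * half + 1L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  kern2 <- outer(g, g)
  kern2 <- kern2 / sum(kern2)
  out <- px
  for (ch in 1:3) {
    xc <- array(px[, , ch], dim = c(dim(px)[1], dim(px)[2], 1L))
    y <- conv2d_fw_cpp(xc, matrix(as.numeric(kern2), ncol = 1), 0, k, 1L, half)
    out[, , ch] <- y[, , 1]
  }
  clamp(out, 0, 1)
}

#' Generate one synthetic annotated slide
#'
#' A pure function of `(spec$seed, image_index)`: calling it twice with the
#' same arguments returns a bit-identical raster and box list. Each cell is
#' a textured, rotated ellipse with class-specific color and shape drawn on
#' a noisy bright background; its label box tightly encloses the cell's
#' visible pixels (truncated cells are clipped to the frame). The whole
#' image may be Gaussian-blurred.
#'
#' @param spec A [slide_spec()].
#' @param image_index Non-negative integer selecting the per-image RNG
#'   stream.
#' @param keep_masks If `TRUE`, attach the per-cell logical masks as
#'   attribute `"masks"` (used by label-tightness checks).
#' @return An [annotated_image()].
#' @export
generate_slide <- function(spec, image_index, keep_masks = FALSE) {
  if (!inherits(spec, "slide_spec")) spec <- do.call(slide_spec, spec)
  stopifnot(image_index >= 0)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  with_seed(spec$seed + image_index, {
    base <- runif(3, 0.78, 0.88)
    px <- array(rep(base, each = H * W), dim = c(H, W, 3))
    px <- px + array(rnorm(H * W * 3, 0, 0.02), dim = c(H, W, 3))
    n_cells <- if (spec$cells_per_image[1] == spec$cells_per_image[2]) {
      spec$cells_per_image[1]
    } else {
      sample(spec$cells_per_image[1]:spec$cells_per_image[2], 1L)
    }
    boxes <- empty_boxes()
    masks <- list()
    minside <- min(H, W)
    i <- 0L
    while (i < n_cells) {
      i <- i + 1L
      cls <- sample.int(spec$n_classes, 1L, prob = spec$class_weights) - 1L
      sty <- class_style(cls, spec$n_classes)
      a <- runif(1, spec$cell_size[1], spec$cell_size[2]) * minside
      aspect <- runif(1, sty$aspect[1], sty$aspect[2])
      # cells thinner than ~4 px would be unresolvable; clamp the minor axis
      b <- max(a / aspect, min(4, a))
      theta <- runif(1, 0, pi)
      truncated <- runif(1) < spec$edge_truncation_prob
      if (truncated) {
        side <- sample.int(4L, 1L)
        off <- runif(1, -0.5, 0.5) * b
        cxp <- switch(side, off, W + off, runif(1, a, W - a), runif(1, a, W - a))
        cyp <- switch(side, runif(1, a, H - a), runif(1, a, H - a), off, H + off)
      } else {
        cxp <- runif(1, a + 1, W - a - 1)
        cyp <- runif(1, a + 1, H - a - 1)
      }
      # render window
      r <- ceiling(a) + 1L
      j0 <- max(1L, floor(cxp - r)); j1 <- min(W, ceiling(cxp + r))
      i0 <- max(1L, floor(cyp - r)); i1 <- min(H, ceiling(cyp + r))
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      X <- outer(rep(1, length(ii)), jj - 0.5) - cxp
      Y <- outer(ii - 0.5, rep(1, length(jj))) - cyp
      Xr <- X * cos(theta) + Y * sin(theta)
      Yr <- -X * sin(theta) + Y * cos(theta)
      m <- (Xr / a)^2 + (Yr / b)^2 <= 1
      if (!any(m)) next
      tex <- switch(sty$texture,
        speckle = matrix(rnorm(length(m), 0, 0.35), nrow(m)),
        stripe  = 0.45 * sin(2 * pi * Xr / pmax(4, a / 2.5)),
        ring    = 0.45 * cos(2 * pi * sqrt((Xr / a)^2 + (Yr / b)^2) * 2.5))
      shade <- 1 - 0.35 * ((Xr / a)^2 + (Yr / b)^2)
      for (ch in 1:3) {
        layer <- px[ii, jj, ch]
        val <- clamp(sty$color[ch] * (shade + tex * 0.3), 0, 1)
        layer[m] <- val[m]
        px[ii, jj, ch] <- layer
      }
      rows <- range(ii[rowSums(m) > 0])
      cols <- range(jj[colSums(m) > 0])
      x1 <- (cols[1] - 1) / W; x2 <- cols[2] / W
      y1 <- (rows[1] - 1) / H; y2 <- rows[2] / H
      boxes <- rbind(boxes, data.frame(class_id = cls,
                                       cx = (x1 + x2) / 2, cy = (y1 + y2) / 2,
                                       w = x2 - x1, h = y2 - y1))
      if (keep_masks) {
        full <- matrix(FALSE, H, W)
        full[ii, jj] <- m
        masks[[length(masks) + 1L]] <- full
      }
    }
    sig <- runif(1, spec$blur_sigma[1], spec$blur_sigma[2])
    px <- blur_image(clamp(px, 0, 1), sig)
    img <- annotated_image(px, boxes, sprintf("slide_%06d", image_index))
    if (keep_masks) attr(img, "masks") <- masks
    img
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG files under `out_dir/images/`, matching YOLO label
#' files under `out_dir/labels/`, and a `dataset.yaml` manifest. The whole
#' dataset is a pure function of `(spec, n_images)`.
#'
#' @param spec A [slide_spec()].
#' @param n_images Number of images (>= 1).
#' @param out_dir Output directory (created if needed).
#' @return A `dataset_index` (see [dataset_index()]).
#' @export
generate_dataset <- function(spec, n_images, out_dir) {
  if (!inherits(spec, "slide_spec")) spec <- do.call(slide_spec, spec)
  stopifnot(n_images >= 1)
  img_dir <- file.path(out_dir, "images")
  lab_dir <- file.path(out_dir, "labels")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(lab_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(img_dir)) stop("I/O failure: cannot create ", img_dir)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images) - 1L) {
    img <- generate_slide(spec, i)
    ip <- file.path(img_dir, paste0(img$image_id, ".png"))
    lp <- file.path(lab_dir, paste0(img$image_id, ".txt"))
    png::writePNG(img$pixels, ip)
    write_yolo_labels(img$boxes, lp)
    rows[[i + 1L]] <- data.frame(image_id = img$image_id, image = ip,
                                 label = lp, n_boxes = nrow(img$boxes))
  }
  files <- do.call(rbind, rows)
  idx <- dataset_index(out_dir, files, spec$n_classes)
  yaml::write_yaml(list(nc = spec$n_classes,
                        names = paste0("class", seq_len(spec$n_classes) - 1L),
                        images = "images", labels = "labels"),
                   file.path(out_dir, "dataset.yaml"))
  idx
}

#' Dataset index
#'
#' A lightweight handle on an on-disk `images/` + `labels/` dataset: the
#' file table plus per-class box counts.
#'
#' @param dir Dataset root directory.
#' @param files `data.frame` with columns `image_id`, `image`, `label`,
#'   `n_boxes`.
#' @param n_classes Number of classes.
#' @param status Optional status string (e.g. balancing warnings).
#' @return An object of class `dataset_index`.
#' @export
dataset_index <- function(dir, files, n_classes, status = "ok") {
  counts <- integer(n_classes)
  for (lp in files$label) {
    b <- read_yolo_labels(lp)
    validate_boxes(b, n_classes)
    if (nrow(b)) {
      t <- tabulate(b$class_id + 1L, nbins = n_classes)
      counts <- counts + t
    }
  }
  structure(list(dir = dir, files = files, n_classes = as.integer(n_classes),
                 class_counts = counts, status = status),
            class = "dataset_index")
}

#' Load a dataset index from a directory
#'
#' @param dir Directory holding `images/`, `labels/` and `dataset.yaml`.
#' @return A `dataset_index`.
#' @export
read_dataset_index <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "dataset.yaml"))
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  ids <- sub("\\.png$", "", basename(imgs))
  labs <- file.path(dir, "labels", paste0(ids, ".txt"))
  nb <- vapply(labs, function(p) nrow(read_yolo_labels(p)), integer(1))
  files <- data.frame(image_id = ids, image = imgs, label = labs, n_boxes = nb)
  dataset_index(dir, files, manifest$nc)
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index: %d images, %d classes, boxes per class [%s], status %s>\n",
              nrow(x$files), x$n_classes,
              paste(x$class_counts, collapse = ", "), x$status))
  invisible(x)
}

# Read one image + labels from an index row into an annotated_image.
load_annotated <- function(index, i) {
  row <- index$files[i, ]
  px <- png::readPNG(row$image)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  annotated_image(px, read_yolo_labels(row$label), row$image_id)
}
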